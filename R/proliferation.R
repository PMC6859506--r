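#' Length-dependent cell proliferation law
#'
#' Defines the per-cell division rate \eqn{G(l)} as a function of current
#' cell length \eqn{l}. A cell divides in a short interval `dt` with
#' probability `G(l) dt`; on division a new node is placed at the cell
#' centre. Three built-in families are provided, all scaled by the intrinsic
#' proliferation rate `beta`:
#'
#' * `"none"`: no proliferation, `G = 0`;
#' * `"constant"`: `G = beta`, independent of length;
#' * `"length_proportional"`: `G = beta * l / a_ref`, so longer cells divide
#'   faster (normalised so `G(a_ref) = beta`);
#' * `"target_length"`: a saturating Hill form
#'   `G = beta * l^shape / (a_ref^shape + l^shape)`, so the rate switches on
#'   as cells approach the reference length `a_ref` and saturates at `beta`;
#' * `"custom"`: any user-supplied non-negative rate function `rate_fn(l)`.
#'
#' @param family Proliferation family name; `"linear"` and `"target"` are
#'   accepted as aliases for `"length_proportional"` and `"target_length"`.
#' @param beta Intrinsic proliferation rate (per unit time), non-negative.
#' @param a_ref Reference (natural) cell length, positive.
#' @param shape Sharpness of the target-length switch, positive.
#' @param rate_fn For `family = "custom"`, a vectorised function mapping cell
#'   lengths to non-negative rates.
#' @return An object of class `proliferation_law`.
#' @examples
#' division_rate(proliferation_law("constant", beta = 0.001), 1)
#' division_rate(proliferation_law("length_proportional", beta = 0.002), 2)
#' @export
proliferation_law <- function(family = c("none", "constant", "length_proportional",
                                         "target_length", "custom", "linear", "target"),
                              beta = 0, a_ref = 1, shape = 4, rate_fn = NULL) {
  family <- match.arg(family)
  family <- switch(family, linear = "length_proportional", target = "target_length", family)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("`beta` must be a single non-negative number", call. = FALSE)
  if (a_ref <= 0 || shape <= 0)
    stop("`a_ref` and `shape` must be positive", call. = FALSE)
  if (family == "custom") {
    if (!is.function(rate_fn))
      stop("family \"custom\" requires a `rate_fn` function", call. = FALSE)
  } else if (!is.null(rate_fn)) {
    stop("`rate_fn` is only used with family \"custom\"", call. = FALSE)
  }
  if (family == "none") beta <- 0
  structure(list(family = family, beta = beta, a_ref = a_ref, shape = shape,
                 rate_fn = rate_fn),
            class = "proliferation_law")
}

#' @export
print.proliferation_law <- function(x, ...) {
  cat(sprintf("<proliferation_law> %s: beta = %g, a_ref = %g\n",
              x$family, x$beta, x$a_ref))
  invisible(x)
}

# integer code used by the compiled steppers
plaw_family_code <- function(plaw) {
  if (is.null(plaw)) return(0L)
  switch(plaw$family, none = 0L, constant = 1L, length_proportional = 2L,
         target_length = 3L, custom = 4L)
}

#' Per-cell division rate
#'
#' @param plaw A [proliferation_law()] (or `NULL` for no proliferation).
#' @param l Cell length(s), positive.
#' @return `G(l)`, the division rate per unit time (non-negative).
#' @export
division_rate <- function(plaw, l) {
  check_lengths(l)
  if (is.null(plaw)) return(rep(0, length(l)))
  g <- switch(plaw$family,
    none = rep(0, length(l)),
    constant = rep(plaw$beta, length(l)),
    length_proportional = plaw$beta * l / plaw$a_ref,
    target_length = plaw$beta * l^plaw$shape / (plaw$a_ref^plaw$shape + l^plaw$shape),
    custom = {
      r <- plaw$rate_fn(l)
      if (length(r) != length(l) || any(!is.finite(r)) || any(r < 0))
        stop("custom proliferation rate must be finite and non-negative", call. = FALSE)
      as.numeric(r)
    })
  g
}
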