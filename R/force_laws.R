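#' Nearest-neighbour cell-cell force law
#'
#' Constructs the interaction law between neighbouring cells in the chain.
#' A cell of length \eqn{l} exerts the force \eqn{F(l) = k\,\mathrm{sign}(a-l)\,|a-l|^n}
#' on its bounding nodes: positive (pushing the nodes apart) when the cell is
#' compressed below its rest length \eqn{a}, negative when stretched, zero at
#' rest. The exponent selects the shape of the law: `n = 1` is a linear
#' spring, `n = 3/2` the Hertz contact law, `n = 3` a cubic law. For
#' fractional exponents the odd-symmetric extension through \eqn{l = a} is
#' used, so the law remains defined for stretched cells.
#'
#' Node motion is overdamped: velocities are net force divided by the
#' viscosity coefficient `eta`, and `alpha = k / eta` is the induced rate
#' constant that appears throughout the continuum limit.
#'
#' @param k Spring stiffness (force per length^`n`), positive.
#' @param a Rest (equilibrium) cell length, positive.
#' @param n Force-law exponent, positive, or one of the names
#'   `"linear"`, `"hertz"`, `"cubic"` (aliases for 1, 3/2, 3).
#' @param eta Viscosity coefficient (force time / length), positive.
#' @return An object of class `force_law` with fields `k`, `a`, `n`, `eta`
#'   and the derived rate `alpha = k/eta`.
#' @examples
#' law <- force_law(k = 1, a = 3, n = "linear")
#' spring_force(law, 2)   # compressed cell pushes outwards
#' diffusivity(law, 1/2)  # alpha / q^2 for the linear law
#' @export
force_law <- function(k = 1, a = 1, n = 1, eta = 1) {
  if (is.character(n)) {
    n <- switch(match.arg(n, c("linear", "hertz", "cubic")),
                linear = 1, hertz = 3 / 2, cubic = 3)
  }
  for (nm in c("k", "a", "n", "eta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive number", call. = FALSE)
  }
  structure(list(k = k, a = a, n = n, eta = eta, alpha = k / eta),
            class = "force_law")
}

#' @export
print.force_law <- function(x, ...) {
  name <- if (x$n == 1) "linear" else if (x$n == 3 / 2) "Hertz" else if (x$n == 3) "cubic" else sprintf("n = %g", x$n)
  cat(sprintf("<force_law> %s: k = %g, a = %g, n = %g, eta = %g (alpha = %g)\n",
              name, x$k, x$a, x$n, x$eta, x$alpha))
  invisible(x)
}

check_lengths <- function(l) {
  if (!is.numeric(l) || any(!is.finite(l)) || any(l <= 0))
    stop("cell lengths must be positive and finite", call. = FALSE)
  l
}

#' Evaluate a force law
#'
#' @param law A [force_law()].
#' @param l Cell length(s), positive.
#' @return `F(l)`, positive for compressed cells (`l < a`), zero at `l = a`.
#' @export
spring_force <- function(law, l) {
  check_lengths(l)
  d <- law$a - l
  if (law$n == 1) return(law$k * d)
  if (law$n == 3) return(law$k * d^3)
  law$k * sign(d) * abs(d)^law$n
}

#' Derivative of a force law
#'
#' Returns \eqn{F'(l) = -n k |a - l|^{n-1}}, needed to evaluate the
#' continuum diffusivity. For exponents below one the derivative diverges at
#' the rest length, where it is not defined.
#'
#' @inheritParams spring_force
#' @return `F'(l)` (non-positive everywhere it is defined).
#' @export
spring_force_deriv <- function(law, l) {
  check_lengths(l)
  if (law$n < 1 && any(l == law$a))
    stop("force derivative is not defined at the rest length for exponents below 1",
         call. = FALSE)
  if (law$n == 1) return(rep(-law$k, length(l)))
  -law$n * law$k * abs(law$a - l)^(law$n - 1)
}

#' Nonlinear diffusion coefficient induced by a force law
#'
#' The coarse-grained density equation is a nonlinear diffusion equation with
#' coefficient \eqn{D(q) = -F'(1/q) / (\eta q^2)}, where `q` is the cell
#' density (cells per unit length, the reciprocal of the local cell length).
#' For the linear law this is \eqn{\alpha / q^2}. `D(q)` is positive wherever
#' the derivative of the force law is (for `n > 1` it degenerates to zero at
#' the rest density `q = 1/a`).
#'
#' @param law A [force_law()].
#' @param q Cell density (number per unit length), positive.
#' @export
diffusivity <- function(law, q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0))
    stop("cell density must be positive and finite", call. = FALSE)
  -spring_force_deriv(law, 1 / q) / (law$eta * q^2)
}
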