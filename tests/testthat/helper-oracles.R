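# Independent oracles used across the suite.

# Exact solution of the linear-law chain ODEs (pinned node 0, free node N):
# x' = alpha (A x + b) is affine with equilibrium x_eq,i = i a, so the
# deviation y = x - x_eq obeys y' = alpha A y with A the symmetric
# tridiagonal second-difference matrix whose last row is (1, -1).
# Solved by eigen-decomposition; entirely independent of the simulation code.
linear_chain_exact <- function(x0, law, t) {
  N <- length(x0) - 1L
  x_eq <- law$a * (0:N)
  A <- diag(-2, N)
  if (N > 1) {
    for (i in 1:(N - 1)) {
      A[i, i + 1] <- 1
      A[i + 1, i] <- 1
    }
  }
  A[N, N] <- -1
  e <- eigen(A, symmetric = TRUE)
  y0 <- x0[-1] - x_eq[-1]
  y <- e$vectors %*% (exp(law$alpha * e$values * t) * crossprod(e$vectors, y0))
  c(0, x_eq[-1] + as.numeric(y))
}

# high-accuracy central-difference derivative
central_diff <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)

# trapezoid rule (local, so the oracle does not share code with the package)
trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
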