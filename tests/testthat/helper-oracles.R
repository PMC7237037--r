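# Reference parameter sets used throughout the tests ------------------------

fig2_params <- function() {
  nondim_params(a = 1, b = 1, s = 0.01, g = 0.15, w = 0.3, p = 1.1, q = 0.1)
}

fig3_fixed <- function(w = 0.5) {
  nondim_params(a = 1, b = 1, s = 0.025, g = 0.375, w = w, p = 0.8, q = 0.1)
}

fig4_fixed <- function(g = 0.5) {
  nondim_params(a = 1, b = 1, s = g / 15, g = g, w = 0.5, p = 0.7, q = 0.2)
}

# Independent numerical oracles ----------------------------------------------

# central-difference Jacobian of a vector field
num_jacobian <- function(f, x, h = 1e-6) {
  n <- length(x)
  J <- matrix(0, length(f(x)), n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}

# damped Newton iteration on a finite-difference Jacobian; independent of the
# package's closed forms and analytic Jacobian
newton_root <- function(f, x0, tol = 1e-12, maxit = 100) {
  x <- x0
  for (i in seq_len(maxit)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) return(x)
    x <- x - solve(num_jacobian(f, x), fx)
  }
  x
}

# rhs evaluated without the non-negativity guard, for root-finding oracles
# that may step slightly outside the positive orthant
rhs_free <- function(params, conversion = TRUE) {
  function(x) {
    F <- x[1]; C <- x[2]; H <- x[3]
    conv <- if (conversion) params$s * (F + C) * H else 0
    c(params$a * F * (1 - F - C - params$w * H),
      C * (1 - F - C - params$p * H) + conv,
      params$b * H * (1 - H - (params$q + params$g) * (F + C)))
  }
}

# Random parameter generators -------------------------------------------------

# coexistence regime: p > w + s, w < 1, q + g < 1
random_coexistence_params <- function() {
  w <- runif(1, 0.05, 0.9)
  q <- runif(1, 0.05, 0.45)
  g <- runif(1, 0.05, min(0.5, 0.95 - q))
  s <- runif(1, 0.01, 0.3)
  p <- w + s + runif(1, 0.05, 1)
  nondim_params(a = runif(1, 0.5, 2), b = runif(1, 0.5, 2),
                s = s, g = g, w = w, p = p, q = q)
}

# converted-farmer wake regime: p < 1 + s, q + g < 1, p < w + s
random_e4_stable_params <- function() {
  w <- runif(1, 0.5, 1.5)
  s <- runif(1, 0.05, 0.5)
  q <- runif(1, 0.05, 0.45)
  g <- runif(1, 0.05, min(0.5, 0.95 - q))
  p_hi <- s + min(1, w)
  p <- runif(1, 0.05, p_hi - 0.02)
  nondim_params(a = runif(1, 0.5, 2), b = runif(1, 0.5, 2),
                s = s, g = g, w = w, p = p, q = q)
}

# broad draws for stability iff-condition checks
random_broad_params <- function() {
  nondim_params(a = runif(1, 0.3, 2.5), b = runif(1, 0.3, 2.5),
                s = runif(1, 0.01, 1.5), g = runif(1, 0.05, 1.5),
                w = runif(1, 0.05, 2), p = runif(1, 0.05, 2.5),
                q = runif(1, 0.05, 1))
}
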