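test_that("the stated fixed points annihilate the homogeneous dynamics", {
  set.seed(11)
  for (i in 1:10) {
    params <- random_broad_params()
    expect_equal(rhs_homogeneous(c(0, 0, 1), params), c(F = 0, C = 0, H = 0))
    expect_equal(rhs_homogeneous(c(1, 0, 0), params), c(F = 0, C = 0, H = 0))
    m <- runif(1)  # any point of the farming-only family is a fixed point
    expect_equal(rhs_homogeneous(c(m, 1 - m, 0), params),
                 c(F = 0, C = 0, H = 0), tolerance = 1e-12)
  }
  # closed-form coexistence state of the reference parameter set
  expect_equal(max(abs(rhs_homogeneous(e5_state(fig2_params()),
                                       fig2_params()))), 0,
               tolerance = 1e-15)
})

test_that("every equilibrium returned is a fixed point to 1e-10", {
  set.seed(12)
  for (i in 1:20) {
    params <- if (i %% 2) random_coexistence_params()
              else random_e4_stable_params()
    eqs <- equilibria(params)
    for (eq in eqs) {
      if (!eq$exists) next
      expect_lt(max(abs(rhs_homogeneous(eq$state, params))), 1e-10)
    }
  }
})

test_that("closed-form equilibria agree with an independent root-finder", {
  set.seed(13)
  for (i in 1:50) {
    params <- random_coexistence_params()
    target <- e5_state(params)
    root <- newton_root(rhs_free(params), target + runif(3, -0.02, 0.02))
    expect_lt(max(abs(root - target)), 1e-8)
  }
  for (i in 1:50) {
    params <- random_e4_stable_params()
    target <- e4_state(params)
    start <- target + runif(3, -0.005, 0.005)  # close start on the F = 0 face
    root <- newton_root(function(x) rhs_free(params)(c(0, x[1], x[2]))[2:3],
                        start[2:3])
    expect_lt(max(abs(root - target[2:3])), 1e-8)
  }
})

test_that("coexistence existence conditions and branches are detected", {
  expect_equal(e5_exists(fig2_params()),
               list(exists = TRUE, branch = "w_below_1"))
  # second branch: p > w + s with 1 < w < p and q + g > 1
  np <- nondim_params(a = 1, b = 1, s = 0.1, g = 1.0, w = 1.5, p = 2.0,
                      q = 0.5)
  expect_equal(e5_exists(np), list(exists = TRUE, branch = "w_above_1"))
  # strictness: p = w + s exactly
  np2 <- nondim_params(a = 1, b = 1, s = 0.2, g = 0.15, w = 0.3, p = 0.5,
                       q = 0.1)
  expect_false(e5_exists(np2)$exists)
  # vanishing denominator w(q+g) = 1
  np3 <- nondim_params(a = 1, b = 1, s = 0.01, g = 1.5, w = 0.5, p = 2.0,
                       q = 0.5)
  expect_equal(np3$w * (np3$q + np3$g), 1)
  expect_false(e5_exists(np3)$exists)
  # degenerate boundaries are reported nonexistent with a warning
  expect_warning(eqs <- equilibria(np2), "degenerate")
  expect_false(eqs$E5$exists)
  expect_true(eqs$E5$degenerate)
})

test_that("the analytic Jacobian matches central differences", {
  set.seed(14)
  for (i in 1:100) {
    params <- random_broad_params()
    x <- runif(3, 0, 1.5)
    J <- jacobian_homogeneous(x, params)
    expect_lt(max(abs(J - num_jacobian(rhs_free(params), x))), 1e-6)
  }
})

test_that("extinction and hunter-gatherer-only eigenstructure is as derived", {
  set.seed(15)
  for (i in 1:20) {
    params <- random_broad_params()
    eqs <- suppressWarnings(equilibria(params))
    # extinction: eigenvalues (a, 1, b), always unstable
    expect_equal(sort(Re(eqs$E1$eigenvalues)),
                 sort(c(params$a, 1, params$b)), tolerance = 1e-10)
    expect_equal(eqs$E1$stability, "unstable")
    # hunter-gatherers alone: eigenvalues a(1-w), 1-p+s, -b
    expect_equal(sort(Re(eqs$E2$eigenvalues)),
                 sort(c(params$a * (1 - params$w),
                        1 - params$p + params$s, -params$b)),
                 tolerance = 1e-10)
  }
})

test_that("closed-form stability conditions match numerical eigenvalues", {
  set.seed(16)
  for (i in 1:200) {
    params <- random_broad_params()
    eqs <- suppressWarnings(equilibria(params))
    # hunter-gatherers alone stable iff w > 1 and p > 1 + s
    expect_equal(eqs$E2$stability == "linearly_stable",
                 params$w > 1 && params$p > 1 + params$s)
    # converted-farmer wake exists and is stable iff
    # p < 1 + s, q + g < 1, p < w + s
    e4_cond <- params$p < 1 + params$s && params$q + params$g < 1 &&
      params$p < params$w + params$s
    expect_equal(eqs$E4$exists && eqs$E4$stability == "linearly_stable",
                 e4_cond)
    # farming-only family: neutrally stable iff q + g > 1
    expect_equal(eqs$E3$stability,
                 if (params$q + params$g > 1) "neutrally_stable"
                 else "undetermined")
  }
})

test_that("a stable coexistence equilibrium excludes the other stable states", {
  set.seed(17)
  found_stable <- 0
  for (i in 1:200) {
    params <- random_broad_params()
    eqs <- suppressWarnings(equilibria(params))
    if (eqs$E5$exists && eqs$E5$stability == "linearly_stable") {
      found_stable <- found_stable + 1
      expect_false(eqs$E2$stability == "linearly_stable")
      expect_false(eqs$E4$exists &&
                     eqs$E4$stability == "linearly_stable")
      expect_false(eqs$E3$stability == "neutrally_stable")
    }
  }
  expect_gt(found_stable, 10)  # regime was actually exercised
})

test_that("the Jacobian determinant at coexistence has the derived sign", {
  set.seed(18)
  for (i in 1:50) {
    params <- random_coexistence_params()
    st <- e5_state(params)
    J <- jacobian_homogeneous(st, params)
    pred <- params$a * params$b *
      (params$p - params$s - params$w) * (params$w - 1) * st[["H"]]^2
    expect_equal(det(J), pred, tolerance = 1e-8)
    # the determinant equals the eigenvalue product
    expect_equal(det(J), Re(prod(eigen(J, only.values = TRUE)$values)),
                 tolerance = 1e-8)
    # p > w + s with w < 1 forces det < 0: no zero/positive real eigenvalue
    expect_lt(det(J), 0)
  }
})

test_that("dropping conversion recovers Lotka-Volterra competition", {
  set.seed(19)
  for (i in 1:20) {
    params <- random_coexistence_params()
    f <- rhs_free(params, conversion = FALSE)
    w <- params$w; p <- params$p; qg <- params$q + params$g
    # textbook two-species coexistence points of the competition model,
    # written here independently of the package's closed forms
    fh <- c(1 - w, 0, 1 - qg) / (1 - w * qg)   # farmers vs hunter-gatherers
    ch <- c(0, 1 - p, 1 - qg) / (1 - p * qg)   # converted vs hunter-gatherers
    expect_lt(max(abs(f(fh))), 1e-12)
    if (all(ch >= 0)) expect_lt(max(abs(f(ch))), 1e-12)
    # and these are the s -> 0 limits of the package's closed forms
    small <- params; small$s <- 1e-12
    expect_equal(unname(e5_state(small)), fh, tolerance = 1e-9)
  }
})

test_that("coexistence densities shift with parameters as derived", {
  mono <- e5_monotonicities(fig2_params())
  expect_equal(mono$sign[mono$component == "F"], c(-1, -1, 1, 1))
  expect_equal(mono$sign[mono$component == "H"], c(0, 1, 0, -1))
  # the reference set has p > 1, so build a p < 1 coexistence set:
  # converted-farmer density then rises with w
  m2 <- e5_monotonicities(fig3_fixed(w = 0.5))
  expect_equal(m2$sign[m2$component == "C" & m2$parameter == "w"], 1)

  # p > 1: converted-farmer density is nonmonotone in w, with the stated peak
  np <- nondim_params(a = 1, b = 1, s = 0.01, g = 0.15, w = 0.3, p = 1.3,
                      q = 0.1)
  m3 <- e5_monotonicities(np)
  expect_true(is.na(m3$sign[m3$component == "C" & m3$parameter == "w"]))
  w_max <- attr(m3, "w_max")
  expect_equal(w_max, 1 - (1 - 1.3) * (1 - 1 / 0.25))
  # finite differences of C in w change sign across the peak
  cw <- function(w) {
    p <- np; p$w <- w
    e5_state(p)[["C"]]
  }
  h <- 1e-4
  expect_gt(cw(w_max - 0.05 + h) - cw(w_max - 0.05), 0)
  expect_lt(cw(w_max + 0.05 + h) - cw(w_max + 0.05), 0)

  expect_error(e5_monotonicities(
    nondim_params(a = 1, b = 1, s = 0.5, g = 0.15, w = 0.3, p = 0.6,
                  q = 0.1)), "require")
})

test_that("monotonicity signs match finite differences of the closed forms", {
  set.seed(20)
  h <- 1e-6
  for (i in 1:20) {
    params <- random_coexistence_params()
    ws <- params$w + params$s
    if (ws + 0.02 >= 1) next
    params$p <- runif(1, ws + 0.02, 1)  # p < 1: every component is monotone
    mono <- e5_monotonicities(params)
    bump <- function(name, delta) {
      pl <- unclass(params)
      if (name == "qg") pl$q <- pl$q + delta else pl[[name]] <- pl[[name]] + delta
      do.call(nondim_params, pl)
    }
    for (par in c("s", "w", "p", "qg")) {
      fd <- (e5_state(bump(par, h)) - e5_state(bump(par, -h))) / (2 * h)
      for (comp in c("F", "C", "H")) {
        sg <- mono$sign[mono$component == comp & mono$parameter == par]
        if (is.na(sg)) next
        if (sg == 0) expect_lt(abs(fd[[comp]]), 1e-8)
        else expect_gt(sg * fd[[comp]], 0)
      }
    }
  }
})

test_that("classification guards against misuse", {
  eqs <- equilibria(fig2_params())
  bad <- eqs$E4
  expect_false(bad$exists)
  expect_error(classify_stability(bad, fig2_params()), "nonexistent")
  expect_error(equilibria(fig2_params(), e3_representative = c(0.7, 0.7)),
               "F \\+ C = 1")
})
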