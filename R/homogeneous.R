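#' Spatially homogeneous dynamics
#'
#' Right-hand side of the non-dimensional three-population system with the
#' diffusion terms removed:
#' \deqn{dF/dt = aF(1 - F - C - wH)}
#' \deqn{dC/dt = C(1 - F - C - pH) + s(F + C)H}
#' \deqn{dH/dt = bH[1 - H - (q + g)(F + C)]}
#'
#' @param state numeric vector `c(F, C, H)` of non-negative densities,
#'   normalized by the carrying capacities.
#' @param params a [nondim_params()] object.
#' @param conversion if `FALSE`, the cultural-conversion term `s(F+C)H` is
#'   dropped, which reduces the system to a three-species Lotka-Volterra
#'   competition model.
#' @return Numeric vector `c(F, C, H)` of growth rates.
#' @export
rhs_homogeneous <- function(state, params, conversion = TRUE) {
  stopifnot(length(state) == 3)
  if (any(state < 0)) stop("densities must be non-negative")
  F <- state[[1]]; C <- state[[2]]; H <- state[[3]]
  conv <- if (conversion) params$s * (F + C) * H else 0
  c(F = params$a * F * (1 - F - C - params$w * H),
    C = C * (1 - F - C - params$p * H) + conv,
    H = params$b * H * (1 - H - (params$q + params$g) * (F + C)))
}

#' Jacobian of the homogeneous dynamics
#'
#' The 3x3 matrix of partial derivatives of [rhs_homogeneous()] with respect
#' to `(F, C, H)`, evaluated at a given state.
#'
#' @inheritParams rhs_homogeneous
#' @return A 3x3 numeric matrix with rows/columns ordered `(F, C, H)`.
#' @export
jacobian_homogeneous <- function(state, params) {
  F <- state[[1]]; C <- state[[2]]; H <- state[[3]]
  a <- params$a; b <- params$b; s <- params$s
  w <- params$w; p <- params$p; qg <- params$q + params$g
  matrix(c(
    a * (1 - 2 * F - C - w * H), -a * F,                         -a * w * F,
    -C + s * H,                  1 - F - 2 * C + (s - p) * H,    s * (F + C) - p * C,
    -b * qg * H,                 -b * qg * H,                    b * (1 - 2 * H - qg * (F + C))
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("F", "C", "H"), c("F", "C", "H")))
}

#' Coexistence equilibrium of all three populations
#'
#' Closed form for the interior fixed point at which initial farmers,
#' converted farmers and hunter-gatherers all persist:
#' \deqn{\hat F = (1-w)(p-w-s) / \{(p-w)[1-w(q+g)]\}}
#' \deqn{\hat C = s(1-w) / \{(p-w)[1-w(q+g)]\}}
#' \deqn{\hat H = (1-q-g) / [1-w(q+g)]}
#'
#' @param params a [nondim_params()] object.
#' @return Named numeric vector `c(F, C, H)`; components may be negative or
#'   non-finite outside the existence region (see [e5_exists()]).
#' @export
e5_state <- function(params) {
  w <- params$w; p <- params$p; s <- params$s
  qg <- params$q + params$g
  den <- (p - w) * (1 - w * qg)
  c(F = (1 - w) * (p - w - s) / den,
    C = s * (1 - w) / den,
    H = (1 - qg) / (1 - w * qg))
}

#' Farming-by-conversion equilibrium
#'
#' Closed form for the fixed point without initial farmers, at which converted
#' farmers coexist with hunter-gatherers.
#'
#' @param params a [nondim_params()] object.
#' @return Named numeric vector `c(F, C, H)` with `F = 0`.
#' @export
e4_state <- function(params) {
  s <- params$s; p <- params$p; qg <- params$q + params$g
  den <- 1 + (s - p) * qg
  c(F = 0, C = (1 + s - p) / den, H = (1 - qg) / den)
}

#' Existence of the three-population coexistence equilibrium
#'
#' The interior equilibrium exists if and only if `p > w + s` together with
#' either `w < 1` and `q + g < 1` (branch `"w_below_1"`) or `1 < w < p` and
#' `q + g > 1` (branch `"w_above_1"`). Boundary cases (any inequality holding
#' with equality, or a vanishing denominator `1 - w(q+g) = 0`) are treated as
#' nonexistent.
#'
#' @param params a [nondim_params()] object.
#' @return A list with elements `exists` (logical) and `branch` (one of
#'   `"w_below_1"`, `"w_above_1"`, `"none"`).
#' @export
e5_exists <- function(params) {
  w <- params$w; p <- params$p; s <- params$s
  qg <- params$q + params$g
  if (w * qg == 1) return(list(exists = FALSE, branch = "none"))
  if (p > w + s && w < 1 && qg < 1)
    return(list(exists = TRUE, branch = "w_below_1"))
  if (p > w + s && w > 1 && w < p && qg > 1)
    return(list(exists = TRUE, branch = "w_above_1"))
  list(exists = FALSE, branch = "none")
}

e4_exists <- function(params) {
  s <- params$s; p <- params$p; qg <- params$q + params$g
  terms <- c(1 + (s - p) * qg, 1 + s - p, 1 - qg)
  if (any(terms == 0)) return(FALSE)
  all(terms > 0) || all(terms < 0)
}

#' All equilibria of the homogeneous system
#'
#' Enumerates the five fixed points of the spatially homogeneous dynamics:
#' total extinction (E1), hunter-gatherers alone at carrying capacity (E2),
#' the farming-only line `F + C = 1, H = 0` (E3, a one-parameter family),
#' converted farmers with hunter-gatherers (E4), and full three-population
#' coexistence (E5). Each equilibrium is returned with its existence flag,
#' Jacobian eigenvalues, and linear stability class (see
#' [classify_stability()]).
#'
#' Equilibria whose existence conditions hold only with equality (e.g.
#' `p = w + s`, `q + g = 1`, or `w(q+g) = 1` for E5) are reported as
#' nonexistent and degenerate, with a warning.
#'
#' @param params a [nondim_params()] object.
#' @param e3_representative length-2 numeric `c(F, C)` with `F + C = 1`,
#'   the point of the E3 family at which eigenvalues are reported.
#' @param eps tolerance on eigenvalue real parts used by the stability
#'   classification.
#' @return An object of class `"equilibrium_set"`: a named list of
#'   `"equilibrium"` objects `E1`..`E5`, each with fields `label`, `exists`,
#'   `state`, `family`, `degenerate`, `eigenvalues`, `stability`.
#' @export
#' @examples
#' fig2 <- nondim_params(a = 1, b = 1, s = 0.01, g = 0.15, w = 0.3,
#'                       p = 1.1, q = 0.1)
#' equilibria(fig2)
equilibria <- function(params, e3_representative = c(1, 0), eps = 1e-9) {
  stopifnot(inherits(params, "nondim_params"))
  if (abs(sum(e3_representative) - 1) > 1e-12 || any(e3_representative < 0))
    stop("the E3 representative must satisfy F + C = 1 with F, C >= 0")
  qg <- params$q + params$g

  mk <- function(label, exists, state = NULL, family = FALSE,
                 degenerate = FALSE) {
    eq <- list(label = label, exists = exists, state = state, family = family,
               degenerate = degenerate, eigenvalues = NULL, stability = NULL)
    class(eq) <- "equilibrium"
    if (exists) {
      eq$eigenvalues <- eigen(jacobian_homogeneous(state, params),
                              only.values = TRUE)$values
      eq$stability <- classify_stability(eq, params, eps = eps)
    }
    eq
  }

  e1 <- mk("E1", TRUE, c(F = 0, C = 0, H = 0))
  e2 <- mk("E2", TRUE, c(F = 0, C = 0, H = 1))
  e3 <- mk("E3", TRUE,
           c(F = e3_representative[[1]], C = e3_representative[[2]], H = 0),
           family = TRUE)

  e4_deg <- any(c(1 + (params$s - params$p) * qg,
                  1 + params$s - params$p, 1 - qg) == 0)
  if (e4_exists(params)) {
    e4 <- mk("E4", TRUE, e4_state(params))
  } else {
    if (e4_deg)
      warning("E4 existence condition holds with equality; ",
              "treating E4 as nonexistent (degenerate)")
    e4 <- mk("E4", FALSE, degenerate = e4_deg)
  }

  ex5 <- e5_exists(params)
  e5_deg <- (params$p == params$w + params$s) || (qg == 1) ||
    (params$w * qg == 1) || (params$w == 1)
  if (ex5$exists) {
    e5 <- mk("E5", TRUE, e5_state(params))
    e5$branch <- ex5$branch
  } else {
    if (e5_deg)
      warning("E5 existence condition holds with equality; ",
              "treating E5 as nonexistent (degenerate)")
    e5 <- mk("E5", FALSE, degenerate = e5_deg)
  }

  structure(list(E1 = e1, E2 = e2, E3 = e3, E4 = e4, E5 = e5),
            class = "equilibrium_set", params = params)
}

#' Linear stability of an equilibrium
#'
#' Classifies an equilibrium by the real parts of its Jacobian eigenvalues:
#' `"linearly_stable"` when all real parts are below `-eps`, `"unstable"` when
#' any real part exceeds `+eps`, and `"undetermined"` when eigenvalues fall
#' inside the `[-eps, eps]` band without any clearly positive one. The
#' farming-only family E3 carries a structural zero eigenvalue (motion along
#' the family); it is classified `"neutrally_stable"` when `q + g > 1`, where
#' the transverse eigenvalues are negative, and `"undetermined"` otherwise.
#'
#' For the coexistence equilibrium E5 no sufficient stability conditions are
#' known; the class returned reflects the numerically computed eigenvalues,
#' and the necessary condition `w < 1` (given existence) can be inspected via
#' the eigenvalues or [e5_exists()].
#'
#' @param eq an `"equilibrium"` object as returned inside [equilibria()], or
#'   a list with at least `state` (and `family`/`label` for E3).
#' @param params a [nondim_params()] object.
#' @param eps half-width of the neutral band on eigenvalue real parts.
#' @return A single string: the stability class.
#' @export
classify_stability <- function(eq, params, eps = 1e-9) {
  if (!isTRUE(eq$exists) && !is.null(eq$exists))
    stop("cannot classify a nonexistent equilibrium")
  if (is.null(eq$state)) stop("equilibrium has no state")
  if (isTRUE(eq$family)) {
    # the family E3 has a structural zero mode; only q + g > 1 is classified
    if (params$q + params$g > 1) return("neutrally_stable")
    return("undetermined")
  }
  ev <- eigen(jacobian_homogeneous(eq$state, params), only.values = TRUE)$values
  re <- Re(ev)
  if (all(re < -eps)) return("linearly_stable")
  if (any(re > eps)) return("unstable")
  "undetermined"
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium %s>%s\n", x$label,
              if (x$family) " (one-parameter family F + C = 1, H = 0)" else ""))
  if (!x$exists) {
    cat("  exists: FALSE", if (x$degenerate) " (degenerate boundary case)", "\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf("  state: F = %.6g, C = %.6g, H = %.6g\n",
              x$state[["F"]], x$state[["C"]], x$state[["H"]]))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  cat("  stability:", x$stability, "\n")
  invisible(x)
}

#' @export
print.equilibrium_set <- function(x, ...) {
  for (eq in x) print(eq)
  invisible(x)
}

#' Tabulate an equilibrium set
#'
#' @param x an `"equilibrium_set"` from [equilibria()].
#' @param ... unused.
#' @return A data frame with one row per equilibrium: label, existence,
#'   state components, eigenvalue real/imaginary parts, and stability class.
#' @export
as.data.frame.equilibrium_set <- function(x, ...) {
  rows <- lapply(x, function(eq) {
    ev <- if (is.null(eq$eigenvalues)) rep(NA_complex_, 3) else eq$eigenvalues
    st <- if (is.null(eq$state)) c(F = NA_real_, C = NA_real_, H = NA_real_)
          else eq$state
    data.frame(label = eq$label, exists = eq$exists,
               F = st[["F"]], C = st[["C"]], H = st[["H"]],
               re_lambda_1 = Re(ev[1]), re_lambda_2 = Re(ev[2]),
               re_lambda_3 = Re(ev[3]),
               im_lambda_1 = Im(ev[1]), im_lambda_2 = Im(ev[2]),
               im_lambda_3 = Im(ev[3]),
               stability = if (is.null(eq$stability)) NA_character_
                           else eq$stability)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter monotonicities of the coexistence equilibrium
#'
#' Signs of the partial derivatives of the coexistence densities
#' `(F, C, H)` with respect to `s`, `w`, `p`, and the combined competition
#' pressure `q + g`, valid throughout the existence region with `w < 1` and
#' `q + g < 1`. The farmer density falls with `w` and `s` and rises with `p`
#' and `q + g`; the converted-farmer density rises with `s` and `q + g` and
#' falls with `p`; in `w` it rises when `p < 1` but has an interior maximum at
#' `w = 1 - (1-p)(1 - 1/(q+g))` when `p > 1`. The hunter-gatherer density
#' depends only on `w` and `q + g`, rising in the former and falling in the
#' latter.
#'
#' @param params a [nondim_params()] object satisfying `p > w + s`, `w < 1`,
#'   `q + g < 1`.
#' @return A data frame with columns `component` (`F`, `C`, `H`), `parameter`
#'   (`s`, `w`, `p`, `qg`) and `sign` (`+1`, `-1`, `0`, or `NA` for the
#'   nonmonotone `C`-in-`w` case, in which case the attribute `"w_max"` holds
#'   the location of the maximum).
#' @export
e5_monotonicities <- function(params) {
  ex <- e5_exists(params)
  if (!ex$exists || ex$branch != "w_below_1")
    stop("monotonicity results require p > w + s, w < 1, q + g < 1")
  qg <- params$q + params$g
  c_in_w <- if (params$p <= 1) 1 else NA_real_
  out <- data.frame(
    component = rep(c("F", "C", "H"), each = 4),
    parameter = rep(c("s", "w", "p", "qg"), times = 3),
    sign = c(-1, -1, +1, +1,      # F
             +1, c_in_w, -1, +1,  # C
             0, +1, 0, -1))       # H
  if (params$p > 1)
    attr(out, "w_max") <- 1 - (1 - params$p) * (1 - 1 / qg)
  out
}
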