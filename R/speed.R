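#' Heuristic minimum traveling-wave speed
#'
#' Linearizing the system ahead of the front, about the hunter-gatherer-only
#' state, gives two candidate dispersion relations: one for a front led by the
#' initial farmers, whose marginal (minimum) speed is `2*sqrt(a*(1-w))`, and
#' one for a front led by the converted farmers, with minimum speed
#' `2*sqrt(1+s-p)`. The governing branch is the larger of `a*(1-w)` and
#' `1+s-p`: below the corresponding speed the decaying eigenvalues become
#' complex and the front profile would oscillate below zero, which is
#' inadmissible for densities. This is the usual pulled-front (linear
#' spreading speed) argument; it is heuristic, not a proof of speed
#' selection.
#'
#' When `w >= 1` the farmer-led expression is undefined and only the
#' converted-farmer branch can apply; if additionally `p >= 1 + s` the
#' hunter-gatherer state is linearly stable and no monostable invasion
#' exists, which is an error.
#'
#' @param params a [nondim_params()] or [dim_params()] object (the latter is
#'   rescaled first).
#' @return An object of class `"speed_analysis"`: a list with `v_min`
#'   (non-dimensional minimum speed), `branch` and `leading_population`
#'   (`"F"` or `"C"`), `degenerate` (`TRUE` on an exact branch tie),
#'   `growth_F = a*(1-w)`, `growth_C = 1+s-p`, and `eigenvalues` (the decaying
#'   co-moving-frame eigenvalues at `v_min`, see [traveling_wave_eigen()]).
#' @export
#' @examples
#' fig2 <- nondim_params(a = 1, b = 1, s = 0.01, g = 0.15, w = 0.3,
#'                       p = 1.1, q = 0.1)
#' heuristic_min_speed(fig2)  # 2 * sqrt(0.7) = 1.67
heuristic_min_speed <- function(params) {
  params <- as_nondim(params)
  A <- params$a * (1 - params$w)   # farmer-led linear growth rate ahead of front
  B <- 1 + params$s - params$p     # converted-farmer-led growth rate
  if (A <= 0 && B <= 0)
    stop("hunter-gatherer-only state is linearly stable (w >= 1 and ",
         "p >= 1 + s): no monostable invasion, heuristic speed undefined")
  lead <- if (A >= B) "F" else "C"
  v <- 2 * sqrt(max(A, B))
  out <- list(v_min = v, branch = lead, leading_population = lead,
              degenerate = isTRUE(all.equal(A, B, tolerance = 1e-12)),
              growth_F = A, growth_C = B,
              eigenvalues = traveling_wave_eigen(v, params))
  class(out) <- "speed_analysis"
  out
}

#' @export
print.speed_analysis <- function(x, ...) {
  cat(sprintf("Heuristic minimum wave speed: v_min = %.6g (%s-led front%s)\n",
              x$v_min, x$leading_population,
              if (x$degenerate) ", branch tie" else ""))
  cat(sprintf("  linear growth ahead of front: farmer branch a(1-w) = %.6g, ",
              x$growth_F))
  cat(sprintf("converted branch 1+s-p = %.6g\n", x$growth_C))
  invisible(x)
}

#' Dimensional minimum wave speed
#'
#' The dimensional counterparts of the two heuristic branches,
#' `2*sqrt(D*r_f*(1-w))` (farmer-led) and `2*sqrt(D*(r_c*(1-p) + e*L))`
#' (converted-farmer-led); the predicted minimum speed is whichever is larger,
#' with a branch included only when its radicand is positive. Equals the
#' speed scale `sqrt(D*r_c)` times the non-dimensional
#' [heuristic_min_speed()].
#'
#' @param params a [dim_params()] object.
#' @return A list with `v_min` (in the units of `sqrt(D * rate)`), `branch`,
#'   and the two branch values `v_F`, `v_C` (`NA` where undefined).
#' @export
dimensional_min_speed <- function(params) {
  stopifnot(inherits(params, "dim_params"))
  radF <- params$D * params$r_f * (1 - params$w)
  radC <- params$D * (params$r_c * (1 - params$p) + params$e * params$L)
  if (radF <= 0 && radC <= 0)
    stop("both branch radicands are non-positive: no monostable invasion")
  vF <- if (radF > 0) 2 * sqrt(radF) else NA_real_
  vC <- if (radC > 0) 2 * sqrt(radC) else NA_real_
  v <- max(vF, vC, na.rm = TRUE)
  list(v_min = v, branch = if (isTRUE(vF >= vC) || is.na(vC)) "F" else "C",
       v_F = vF, v_C = vC)
}

#' Traveling-wave phase-space system
#'
#' In the co-moving coordinate `z = x - v*t` the three reaction-diffusion
#' equations become a six-dimensional first-order ODE system in
#' `(F, U, C, V, H, W)`, where `U = F'`, `V = C'`, `W = H'`:
#' \deqn{F' = U, \quad U' = -aF(1-F-C-wH) - vU}
#' \deqn{C' = V, \quad V' = -[C(1-F-C-pH) + s(F+C)H] - vV}
#' \deqn{H' = W, \quad W' = -bH[1-H-(q+g)(F+C)] - vW}
#' The system is exposed for eigenstructure checks at the state ahead of the
#' front; the full wave profile is obtained by PDE simulation
#' ([simulate_wave()]), not by shooting.
#'
#' @param state numeric vector `c(F, U, C, V, H, W)`.
#' @param v wave speed, `v > 0`.
#' @param params a [nondim_params()] object.
#' @return Numeric vector of the six derivatives.
#' @export
traveling_wave_rhs <- function(state, v, params) {
  stopifnot(length(state) == 6, v > 0)
  F <- state[[1]]; U <- state[[2]]; C <- state[[3]]
  V <- state[[4]]; H <- state[[5]]; W <- state[[6]]
  a <- params$a; b <- params$b; s <- params$s
  w <- params$w; p <- params$p; qg <- params$q + params$g
  c(F = U,
    U = -a * F * (1 - F - C - w * H) - v * U,
    C = V,
    V = -(C * (1 - F - C - p * H) + s * (F + C) * H) - v * V,
    H = W,
    W = -b * H * (1 - H - qg * (F + C)) - v * W)
}

#' Decaying eigenvalues ahead of the front
#'
#' Closed-form eigenvalues of the co-moving-frame linearization at the
#' hunter-gatherer-only state `(F,U,C,V,H,W) = (0,0,0,0,1,0)` that can be
#' negative or have negative real part:
#' \deqn{\lambda_\pm = (-v \pm \sqrt{v^2 - 4a(1-w)})/2}
#' \deqn{\kappa_\pm = (-v \pm \sqrt{v^2 - 4(1-p+s)})/2}
#' \deqn{\mu_- = (-v - \sqrt{v^2 + 4b})/2}
#' The `kappa` pair governs the converted-farmer component and is reported
#' only when `1 - p + s > 0`; `lambda` may be complex below the farmer-branch
#' minimum speed.
#'
#' @param v wave speed, `v > 0`.
#' @param params a [nondim_params()] object.
#' @return Named list of complex numbers `lambda_plus`, `lambda_minus`,
#'   `kappa_plus` (`NULL` if `1-p+s <= 0`), `kappa_minus`, `mu_minus`.
#' @export
traveling_wave_eigen <- function(v, params) {
  stopifnot(v > 0)
  discF <- as.complex(v^2 - 4 * params$a * (1 - params$w))
  discC <- as.complex(v^2 - 4 * (1 - params$p + params$s))
  out <- list(lambda_plus = (-v + sqrt(discF)) / 2,
              lambda_minus = (-v - sqrt(discF)) / 2,
              kappa_plus = if (1 - params$p + params$s > 0)
                (-v + sqrt(discC)) / 2 else NULL,
              kappa_minus = (-v - sqrt(discC)) / 2,
              mu_minus = (-v - sqrt(v^2 + 4 * params$b)) / 2)
  lapply(out, function(z) if (!is.null(z) && Im(z) == 0) Re(z) else z)
}

#' Admissibility of a candidate front speed
#'
#' A front invading the hunter-gatherer-only state at speed `v` is admissible
#' under the linear (pulled-front) argument only if the decaying eigenvalues
#' of the governing branch are real, i.e. `v^2 >= 4a(1-w)` for a farmer-led
#' front or `v^2 >= 4(1+s-p)` for a converted-farmer-led front: complex
#' eigenvalues would make the leading density oscillate about zero. A small
#' relative tolerance admits speeds quoted at rounded precision at the
#' marginal boundary.
#'
#' @param v candidate speed.
#' @param params a [nondim_params()] object.
#' @param tol relative tolerance on the comparison with the minimum speed.
#' @return `TRUE` if the speed admits a non-oscillating entry, else `FALSE`.
#' @export
#' @examples
#' fig2 <- nondim_params(a = 1, b = 1, s = 0.01, g = 0.15, w = 0.3,
#'                       p = 1.1, q = 0.1)
#' front_entry_check(1.67, fig2)  # TRUE: marginal speed, rounded
#' front_entry_check(1.0, fig2)   # FALSE: decaying eigenvalues complex
front_entry_check <- function(v, params, tol = 0.01) {
  sa <- heuristic_min_speed(params)
  v >= sa$v_min * (1 - tol)
}
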