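#' Spatial grid for the one-dimensional habitat
#'
#' A uniform grid on `[0, l]` with spacing `dx`, plus the length `d` of the
#' initial farmer-occupied block at the left end. The defaults `l = 800`,
#' `d = 80` place the founding farmer population on the leftmost tenth of the
#' habitat, leaving ample room for the front to travel before feeling the far
#' boundary.
#'
#' @param l domain length (non-dimensional).
#' @param d initial farmer-block length, `0 < d < l`.
#' @param dx grid spacing; the number of points is `n = l/dx + 1`.
#' @return An object of class `"wave_grid"` with fields `l`, `d`, `n`, `dx`,
#'   and the coordinate vector `x`.
#' @export
wave_grid <- function(l = 800, d = 80, dx = 1) {
  stopifnot(l > 0, dx > 0, d > 0, d < l)
  n <- round(l / dx) + 1
  if (n < 3) stop("grid must have at least 3 points")
  if (abs((n - 1) * dx - l) > 1e-8 * l)
    stop("domain length l must be a multiple of dx")
  structure(list(l = l, d = d, n = n, dx = dx, x = seq(0, l, length.out = n)),
            class = "wave_grid")
}

#' Step initial conditions
#'
#' Farmers at carrying capacity and no hunter-gatherers on the initial block
#' `[0, d]`; hunter-gatherers at carrying capacity and no farmers beyond it:
#' `F = 1, C = 0, H = 0` for `x <= d` and `F = 0, C = 0, H = 1` for `x > d`.
#' The grid point nearest `d` is assigned to the farmer block.
#'
#' @param grid a [wave_grid()] object.
#' @return An object of class `"field_state"`: list with time `t = 0`, the
#'   three density vectors `F`, `C`, `H`, and the grid.
#' @export
initial_condition <- function(grid) {
  stopifnot(inherits(grid, "wave_grid"))
  inblock <- grid$x <= grid$d + grid$dx / 2
  field_state(t = 0, F = as.numeric(inblock), C = numeric(grid$n),
              H = as.numeric(!inblock), grid = grid)
}

#' Construct a field state
#'
#' @param t time.
#' @param F,C,H numeric density vectors over the grid, all non-negative.
#' @param grid a [wave_grid()] object.
#' @return An object of class `"field_state"`.
#' @export
field_state <- function(t, F, C, H, grid) {
  stopifnot(length(F) == grid$n, length(C) == grid$n, length(H) == grid$n)
  if (any(c(F, C, H) < 0)) stop("densities must be non-negative")
  structure(list(t = t, F = F, C = C, H = H, grid = grid),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("<field_state t = %.4g on [0, %g], n = %d>\n",
              x$t, x$grid$l, x$grid$n))
  cat(sprintf("  ranges: F [%.3g, %.3g], C [%.3g, %.3g], H [%.3g, %.3g]\n",
              min(x$F), max(x$F), min(x$C), max(x$C), min(x$H), max(x$H)))
  invisible(x)
}

# discrete Laplacian with zero-flux (mirrored ghost point) boundaries
laplacian_neumann <- function(u, dx) {
  n <- length(u)
  left <- c(u[2], u[-n])    # ghost: u[0] = u[2]
  right <- c(u[-1], u[n - 1])  # ghost: u[n+1] = u[n-1]
  (left - 2 * u + right) / dx^2
}

#' Advance the fields one time step
#'
#' Explicit Euler step of the method-of-lines discretization: second-order
#' central differences for the diffusion term with mirrored ghost points at
#' both ends (zero-flux, i.e. reflecting boundaries), and the pointwise
#' reaction terms of the non-dimensional system. Round-off undershoots below
#' zero are clipped; an undershoot beyond `1e-8` in magnitude indicates an
#' unstable step size and raises an error.
#'
#' @param state a [field_state()] object.
#' @param dt time increment; must satisfy the diffusive stability constraint
#'   `dt <= dx^2/2` (the default used by [simulate_wave()] is `0.05*dx^2`).
#' @param params a [nondim_params()] object.
#' @param reaction if `FALSE`, only diffusion is applied (used for
#'   conservation checks).
#' @return The advanced `"field_state"`, with attribute `"clipped"` giving
#'   the total density removed by clipping in this step.
#' @export
step_fields <- function(state, dt, params, reaction = TRUE) {
  grid <- state$grid
  F <- state$F; C <- state$C; H <- state$H
  if (reaction) {
    tot <- F + C
    rF <- params$a * F * (1 - tot - params$w * H)
    rC <- C * (1 - tot - params$p * H) + params$s * tot * H
    rH <- params$b * H * (1 - H - (params$q + params$g) * tot)
  } else {
    rF <- rC <- rH <- 0
  }
  Fn <- F + dt * (laplacian_neumann(F, grid$dx) + rF)
  Cn <- C + dt * (laplacian_neumann(C, grid$dx) + rC)
  Hn <- H + dt * (laplacian_neumann(H, grid$dx) + rH)
  if (any(!is.finite(Fn)) || any(!is.finite(Cn)) || any(!is.finite(Hn)))
    stop(sprintf("integration failed (non-finite densities) at t = %.6g; ",
                 state$t + dt), "reduce dt")
  low <- min(Fn, Cn, Hn)
  if (low < -1e-8)
    stop(sprintf(paste0("negative densities (%.3g) beyond round-off at ",
                        "t = %.6g; reduce dt"), low, state$t + dt))
  clipped <- -(sum(pmin(Fn, 0)) + sum(pmin(Cn, 0)) + sum(pmin(Hn, 0)))
  out <- field_state(t = state$t + dt, F = pmax(Fn, 0), C = pmax(Cn, 0),
                     H = pmax(Hn, 0), grid = grid)
  attr(out, "clipped") <- clipped
  out
}

#' Locate the advancing farming front
#'
#' The front is defined on the total farming density `F + C`: its position is
#' the largest `x` at which `F + C >= threshold`, linearly interpolated
#' between grid points. The default threshold, half the farming carrying
#' capacity, tracks both farmer-led and converted-farmer-led fronts whose
#' wake plateau exceeds it; for low-plateau wakes pass a smaller threshold
#' (e.g. half the predicted wake density).
#'
#' @param state a [field_state()] object.
#' @param threshold density level defining the front.
#' @return The front position, or `NA` (with attribute `"no_front"`) if
#'   `F + C` never reaches the threshold.
#' @export
front_position <- function(state, threshold = 0.5) {
  f <- state$F + state$C
  x <- state$grid$x
  above <- which(f >= threshold)
  if (!length(above))
    return(structure(NA_real_, no_front = TRUE))
  i <- max(above)
  if (i == length(f)) return(x[i])
  # interpolate the downcrossing between points i and i+1
  x[i] + state$grid$dx * (f[i] - threshold) / (f[i] - f[i + 1])
}

#' Fit the wave speed from a front trajectory
#'
#' Least-squares slope of front position versus time over the last half of
#' the recorded observations, discarding the earlier half as initial
#' transient. At least 10 observations must remain after exclusion.
#'
#' @param times,positions paired numeric vectors of observation times and
#'   front positions (`NA` positions are dropped).
#' @return A list with `speed` (fitted slope), `stderr` (its standard
#'   error), and `n_used`.
#' @export
estimate_speed <- function(times, positions) {
  keep <- is.finite(positions) & is.finite(times)
  times <- times[keep]; positions <- positions[keep]
  m <- length(times)
  start <- floor(m / 2) + 1
  if (m - start + 1 < 10)
    stop("too few front observations after transient exclusion (need >= 10)")
  fit <- stats::lm(positions[start:m] ~ times[start:m])
  # summary.lm warns on an exactly linear trajectory; stderr 0 is meaningful
  co <- suppressWarnings(summary(fit)$coefficients)
  list(speed = unname(co[2, 1]), stderr = unname(co[2, 2]),
       n_used = m - start + 1)
}

#' Simulate the invasion wave
#'
#' Integrates the non-dimensional three-population reaction-diffusion system
#' from the step initial conditions ([initial_condition()]) until `t_end`,
#' recording the front position ([front_position()]) at regular observation
#' intervals. Integration stops early, with a flag, once the front enters the
#' right tenth of the domain, where the reflecting boundary contaminates the
#' wave. The asymptotic speed is then fitted on the late-time window
#' ([estimate_speed()]) and the wake state is classified against the model's
#' equilibria ([wake_equilibrium()]).
#'
#' @param params a [nondim_params()] object.
#' @param grid a [wave_grid()] object.
#' @param t_end final time (non-dimensional).
#' @param dt time step; default `0.05 * dx^2`. The explicit-Euler stability
#'   limit for unit diffusivity is `0.5 * dx^2`; the smaller default also
#'   resolves the O(1) reaction timescale, which dominates the accuracy of
#'   the fitted front speed (temporal refinement beyond it changes the
#'   speed by well under 1%).
#' @param observe_every interval between front observations.
#' @param threshold front-tracking density level, see [front_position()].
#' @param state0 optional initial `"field_state"` overriding
#'   [initial_condition()].
#' @param wake_lag distance behind the final front at which the wake is
#'   sampled.
#' @return An object of class `"wave_result"`: list with `front_times`,
#'   `front_positions`, `speed`, `speed_stderr`, `wake_state`, `wake_label`,
#'   `profile_final` (a `"field_state"`), `stopped_early`, `clipped_total`,
#'   plus the `params`, `grid` and settings used.
#' @export
#' @examples
#' \donttest{
#' fig2 <- nondim_params(a = 1, b = 1, s = 0.01, g = 0.15, w = 0.3,
#'                       p = 1.1, q = 0.1)
#' res <- simulate_wave(fig2, wave_grid(), t_end = 450)
#' res$speed        # about 1.6; compare heuristic_min_speed(fig2)$v_min
#' res$wake_label   # "E5": all three populations persist behind the front
#' }
simulate_wave <- function(params, grid = wave_grid(), t_end = 450,
                          dt = 0.05 * grid$dx^2, observe_every = 1,
                          threshold = 0.5, state0 = NULL, wake_lag = 150) {
  stopifnot(inherits(params, "nondim_params"), t_end > 0)
  state <- if (is.null(state0)) initial_condition(grid) else state0
  steps_per_obs <- max(1L, round(observe_every / dt))
  n_obs <- floor(t_end / (steps_per_obs * dt))
  ft <- fp <- numeric(0)
  clipped <- 0
  stopped_early <- FALSE
  boundary_zone <- 0.9 * grid$l
  ft[1] <- state$t
  fp[1] <- front_position(state, threshold)
  for (k in seq_len(n_obs)) {
    for (j in seq_len(steps_per_obs)) {
      state <- step_fields(state, dt, params)
      clipped <- clipped + attr(state, "clipped")
    }
    pos <- front_position(state, threshold)
    ft[k + 1] <- state$t
    fp[k + 1] <- pos
    if (is.finite(pos) && pos >= boundary_zone) {
      stopped_early <- TRUE
      break
    }
  }
  res <- list(front_times = ft, front_positions = fp,
              speed = NA_real_, speed_stderr = NA_real_,
              wake_state = NULL, wake_label = NA_character_,
              profile_final = state, stopped_early = stopped_early,
              clipped_total = clipped, params = params, grid = grid,
              threshold = threshold, dt = dt)
  class(res) <- "wave_result"
  fit <- tryCatch(estimate_speed(ft, fp), error = function(e) NULL)
  if (!is.null(fit)) {
    res$speed <- fit$speed
    res$speed_stderr <- fit$stderr
  }
  wake <- tryCatch(wake_equilibrium(res, params, lag = wake_lag),
                   error = function(e) NULL)
  if (!is.null(wake)) {
    res$wake_label <- wake$label
    res$wake_state <- wake$state
  }
  res
}

#' @export
print.wave_result <- function(x, ...) {
  cat("<wave_result>\n")
  cat(sprintf("  final time %.4g%s; %d front observations\n",
              x$profile_final$t,
              if (x$stopped_early) " (stopped near right boundary)" else "",
              length(x$front_times)))
  if (is.finite(x$speed))
    cat(sprintf("  fitted front speed: %.4f (se %.2g)\n", x$speed,
                x$speed_stderr))
  if (!is.na(x$wake_label)) {
    cat(sprintf("  wake equilibrium: %s at F = %.3f, C = %.3f, H = %.3f\n",
                x$wake_label, x$wake_state[["F"]], x$wake_state[["C"]],
                x$wake_state[["H"]]))
  }
  invisible(x)
}

#' Classify the state behind the front
#'
#' Samples the densities a fixed distance behind the final front position and
#' matches them against the existing equilibria of the homogeneous system by
#' nearest Euclidean distance. For the farming-only family E3 the comparison
#' point is the orthogonal projection of the sample onto the line
#' `F + C = 1, H = 0`. A label is returned only when every component of the
#' sample is within `tol` of the matched equilibrium; otherwise
#' `"unconverged"`. The front must have advanced at least 200 length units so
#' that a genuine wake exists.
#'
#' @param result a `"wave_result"` from [simulate_wave()].
#' @param params a [nondim_params()] object.
#' @param lag sampling distance behind the final front position.
#' @param tol per-component matching tolerance.
#' @return A list with `label` (equilibrium label or `"unconverged"`),
#'   `state` (the sampled `c(F, C, H)`), and `x_sample`.
#' @export
wake_equilibrium <- function(result, params, lag = 150, tol = 0.02) {
  fp <- result$front_positions
  fp <- fp[is.finite(fp)]
  if (!length(fp)) stop("no front was ever detected")
  advance <- fp[length(fp)] - fp[1]
  if (advance < 200)
    stop(sprintf("front advanced only %.3g length units (need >= 200) ",
                 advance), "for a meaningful wake sample")
  prof <- result$profile_final
  x_s <- fp[length(fp)] - lag
  i <- which.min(abs(prof$grid$x - x_s))
  sample <- c(F = prof$F[i], C = prof$C[i], H = prof$H[i])

  eqs <- suppressWarnings(equilibria(params))
  best <- NULL; best_d <- Inf; best_ref <- NULL
  for (eq in eqs) {
    if (!eq$exists) next
    ref <- if (eq$family) {
      # nearest point of the F + C = 1, H = 0 family (clamped to F, C >= 0)
      m <- (sample[["F"]] - sample[["C"]] + 1) / 2
      m <- min(max(m, 0), 1)
      c(F = m, C = 1 - m, H = 0)
    } else eq$state
    d <- sqrt(sum((sample - ref)^2))
    if (d < best_d) {
      best_d <- d; best <- eq$label; best_ref <- ref
    }
  }
  label <- if (!is.null(best) && all(abs(sample - best_ref) <= tol)) best
           else "unconverged"
  list(label = label, state = sample, x_sample = prof$grid$x[i])
}
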