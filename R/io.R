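#' Read a parameter configuration file
#'
#' Reads a flat key-value configuration in YAML (or `key = value` / `key:
#' value` plain text) and builds a parameter object. A file supplying
#' `a, b, s, g, w, p, q` yields a [nondim_params()]; one supplying
#' `D, r_f, r_c, r_h, K, L, e, w, p, q` yields a [dim_params()]. Extra keys
#' `l`, `d`, `dx`, `dt`, `t_end`, `threshold`, `observe_every` are returned
#' as solver settings.
#'
#' @param path path to the configuration file.
#' @return A list with `params` (a parameter object) and `settings`
#'   (named list of any solver keys present).
#' @export
read_params_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("configuration must be a flat key-value mapping")
  nd_keys <- c("a", "b", "s", "g", "w", "p", "q")
  dim_keys <- c("D", "r_f", "r_c", "r_h", "K", "L", "e", "w", "p", "q")
  params <- if (all(dim_keys %in% names(vals))) {
    do.call(dim_params, vals[dim_keys])
  } else if (all(nd_keys %in% names(vals))) {
    do.call(nondim_params, vals[nd_keys])
  } else {
    stop("configuration must supply either the non-dimensional keys (",
         paste(nd_keys, collapse = ", "), ") or the dimensional keys (",
         paste(dim_keys, collapse = ", "), ")")
  }
  setting_keys <- c("l", "d", "dx", "dt", "t_end", "threshold",
                    "observe_every")
  list(params = params, settings = vals[intersect(names(vals), setting_keys)])
}

#' Write an equilibrium report
#'
#' Serializes an equilibrium set as CSV (one row per equilibrium: label,
#' existence, state components, eigenvalue real and imaginary parts,
#' stability class) and/or JSON.
#'
#' @param eqs an `"equilibrium_set"` from [equilibria()].
#' @param csv,json output paths (`NULL` to skip either).
#' @return Invisibly, the report data frame.
#' @export
write_equilibrium_report <- function(eqs, csv = NULL, json = NULL) {
  df <- as.data.frame(eqs)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(df, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  invisible(df)
}

#' Write a wave-speed report
#'
#' Serializes a [heuristic_min_speed()] analysis (and, when dimensional
#' parameters are supplied, the corresponding dimensional speed) as JSON.
#'
#' @param analysis a `"speed_analysis"` object.
#' @param path output path.
#' @param dim_speed optional result of [dimensional_min_speed()].
#' @return Invisibly, the list written.
#' @export
write_speed_report <- function(analysis, path, dim_speed = NULL) {
  ev <- lapply(analysis$eigenvalues, function(z) {
    if (is.null(z)) NULL
    else if (is.complex(z)) list(re = Re(z), im = Im(z))
    else z
  })
  out <- list(
    v_min = analysis$v_min,
    branch = analysis$branch,
    leading_population = analysis$leading_population,
    degenerate = analysis$degenerate,
    governing_expression = if (analysis$branch == "F")
      "2*sqrt(a*(1-w))" else "2*sqrt(1+s-p)",
    eigenvalues = ev)
  if (!is.null(dim_speed)) out$dimensional <- dim_speed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}

#' Write a simulation result bundle
#'
#' Writes the final profile and the front trajectory as CSV and a summary
#' (speed, wake) as JSON into a directory.
#'
#' @param result a `"wave_result"` from [simulate_wave()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_wave_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prof <- result$profile_final
  p1 <- file.path(dir, "profile.csv")
  utils::write.csv(data.frame(x = prof$grid$x, F = prof$F, C = prof$C,
                              H = prof$H), p1, row.names = FALSE)
  p2 <- file.path(dir, "front.csv")
  utils::write.csv(data.frame(t = result$front_times,
                              x_front = result$front_positions),
                   p2, row.names = FALSE)
  p3 <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    speed = result$speed, speed_stderr = result$speed_stderr,
    wake_label = result$wake_label,
    wake_state = as.list(result$wake_state),
    stopped_early = result$stopped_early,
    t_final = prof$t, params = unclass(result$params),
    grid = list(l = result$grid$l, d = result$grid$d, dx = result$grid$dx),
    dt = result$dt, threshold = result$threshold),
    p3, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(c(profile = p1, front = p2, summary = p3))
}
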