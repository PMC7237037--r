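#' Non-dimensional model parameters
#'
#' Constructs the seven composite parameters of the rescaled three-population
#' system. Densities are measured in units of the carrying capacities (farmers
#' `K`, hunter-gatherers `L`), lengths in units of `sqrt(D/r_c)` and times in
#' units of `1/r_c`, where `r_c` is the intrinsic growth rate of the converted
#' farmers.
#'
#' @param a ratio `r_f/r_c` of the initial-farmer to converted-farmer growth
#'   rate.
#' @param b ratio `r_h/r_c` of the hunter-gatherer to converted-farmer growth
#'   rate.
#' @param s rescaled conversion rate `e*L/r_c`.
#' @param g rescaled conversion rate `e*K/r_h`.
#' @param w competitive effect of hunter-gatherers on initial farmers.
#' @param p competitive effect of hunter-gatherers on converted farmers.
#' @param q competitive effect of farmers (both types) on hunter-gatherers.
#'
#' @details All parameters must be strictly positive. The intra-subsistence
#'   competition coefficients are fixed at 1 by the rescaling, so `w`, `p` and
#'   `q` measure inter-subsistence competition only.
#'
#' @return An object of class `"nondim_params"`, a named list with the seven
#'   components.
#' @seealso [dim_params()], [nondimensionalize()]
#' @export
#' @examples
#' nondim_params(a = 1, b = 1, s = 0.01, g = 0.15, w = 0.3, p = 1.1, q = 0.1)
nondim_params <- function(a, b, s, g, w, p, q) {
  vals <- c(a = a, b = b, s = s, g = g, w = w, p = p, q = q)
  check_positive(vals)
  structure(as.list(vals), class = "nondim_params")
}

#' Dimensional model parameters
#'
#' The ten original parameters of the dimensional three-population system:
#' a common diffusion constant, three intrinsic growth rates, two carrying
#' capacities, a conversion rate, and three dimensionless competition
#' coefficients.
#'
#' @param D diffusion constant (area/time), the same for all three
#'   populations.
#' @param r_f,r_c,r_h intrinsic growth rates (1/time) of initial farmers,
#'   converted farmers, and hunter-gatherers.
#' @param K carrying capacity (density) of initial and converted farmers
#'   combined.
#' @param L carrying capacity (density) of hunter-gatherers.
#' @param e conversion rate (1/(density*time)) of hunter-gatherers to farming
#'   by contact with farmers.
#' @param w,p,q dimensionless competition coefficients, as in
#'   [nondim_params()].
#'
#' @return An object of class `"dim_params"`.
#' @export
dim_params <- function(D, r_f, r_c, r_h, K, L, e, w, p, q) {
  vals <- c(D = D, r_f = r_f, r_c = r_c, r_h = r_h, K = K, L = L, e = e,
            w = w, p = p, q = q)
  check_positive(vals)
  structure(as.list(vals), class = "dim_params")
}

check_positive <- function(vals) {
  if (any(!is.finite(unlist(vals))))
    stop("all parameters must be finite numbers", call. = FALSE)
  bad <- names(vals)[unlist(vals) <= 0]
  if (length(bad))
    stop("all parameters must be strictly positive; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Rescale dimensional parameters to non-dimensional form
#'
#' Computes `a = r_f/r_c`, `b = r_h/r_c`, `s = e*L/r_c`, `g = e*K/r_h` and
#' passes `w`, `p`, `q` through, together with the characteristic scales that
#' undo the rescaling: length `sqrt(D/r_c)`, time `1/r_c`, and speed
#' `sqrt(D*r_c)`. A dimensional wave speed equals the speed scale times the
#' corresponding non-dimensional speed.
#'
#' @param params a [dim_params()] object.
#' @return A list with components `params` (a [nondim_params()] object) and
#'   `scales` (named list `length`, `time`, `speed`).
#' @export
#' @examples
#' dp <- dim_params(D = 2, r_f = 0.5, r_c = 0.5, r_h = 0.5, K = 15, L = 1,
#'                  e = 0.005, w = 0.3, p = 1.1, q = 0.1)
#' nondimensionalize(dp)
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "dim_params"))
  np <- with(params, nondim_params(
    a = r_f / r_c, b = r_h / r_c,
    s = e * L / r_c, g = e * K / r_h,
    w = w, p = p, q = q))
  scales <- list(length = sqrt(params$D / params$r_c),
                 time = 1 / params$r_c,
                 speed = sqrt(params$D * params$r_c))
  list(params = np, scales = scales)
}

#' Ratio of farmer to hunter-gatherer carrying capacity
#'
#' Recovers `K/L` from the composite parameters: since `s = e*L/r_c` and
#' `g = e*K/r_h`, the ratio is `K/L = b*g/s`.
#'
#' @param params a [nondim_params()] object.
#' @return The ratio `K/L` as a single number.
#' @export
#' @examples
#' carrying_capacity_ratio(
#'   nondim_params(a = 1, b = 1, s = 0.01, g = 0.15, w = 0.3, p = 1.1, q = 0.1))
carrying_capacity_ratio <- function(params) {
  stopifnot(inherits(params, "nondim_params"))
  if (params$s == 0) stop("carrying-capacity ratio undefined for s = 0")
  params$b * params$g / params$s
}

#' @export
print.nondim_params <- function(x, ...) {
  cat("Non-dimensional three-population parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.dim_params <- function(x, ...) {
  cat("Dimensional three-population parameters:\n")
  print(unlist(x))
  invisible(x)
}

as_nondim <- function(params) {
  if (inherits(params, "nondim_params")) return(params)
  if (inherits(params, "dim_params")) return(nondimensionalize(params)$params)
  stop("expected a 'nondim_params' or 'dim_params' object")
}
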