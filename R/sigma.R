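#' Dispersion model parameters
#'
#' @param sigma_scheme name of the plume-spread scheme; `"briggs_rural"`
#'   (open-country Briggs curves keyed to Pasquill stability class) is the
#'   default and only built-in scheme; additional schemes can be registered
#'   with [register_sigma_scheme()].
#' @param n_reflections number of mixing-lid image-source pairs (default 2;
#'   ground reflection is always included).
#' @param line_tol relative convergence tolerance for the finite-line
#'   integral (default 1e-3).
#' @param area_tol relative convergence tolerance for the area-source slice
#'   decomposition (default 1e-2).
#' @param min_downwind minimum along-wind source-receptor distance m; closer
#'   (or upwind) contributions are zero (default 1).
#' @param max_doublings cap on refinement doublings (default 18).
#' @param mixed_limit_factor switch to the vertically well-mixed limit when
#'   the effective vertical spread exceeds this multiple of the mixing height
#'   (default 1.6).
#' @return list of class `dispersion_params`.
#' @export
dispersion_params <- function(sigma_scheme = "briggs_rural",
                              n_reflections = 2,
                              line_tol = 1e-3,
                              area_tol = 1e-2,
                              min_downwind = 1,
                              max_doublings = 18,
                              mixed_limit_factor = 1.6) {
  stopifnot(line_tol > 0, area_tol > 0, min_downwind > 0, n_reflections >= 0)
  structure(list(sigma_scheme = sigma_scheme, n_reflections = n_reflections,
                 line_tol = line_tol, area_tol = area_tol,
                 min_downwind = min_downwind, max_doublings = max_doublings,
                 mixed_limit_factor = mixed_limit_factor),
            class = "dispersion_params")
}

#' Pasquill stability class from Monin-Obukhov length
#'
#' Golder-style step mapping on 1/L, monotone from A (strongly unstable,
#' small negative L) through D (near-neutral, |L| >= 500 m) to F (strongly
#' stable, small positive L). Fixed boundaries (in 1/L, units 1/m):
#' A: 1/L <= -0.07; B: (-0.07, -0.02]; C: (-0.02, -0.002]; D: |1/L| < 0.002;
#' E: [0.002, 0.02); F: >= 0.02.
#'
#' @param L Monin-Obukhov length m, `|L| > 0`; vectorised.
#' @return character vector of classes in `A`..`F`.
#' @export
stability_class <- function(L) {
  stopifnot(all(L != 0))
  s <- 1 / L
  cls <- character(length(s))
  cls[s <= -0.07] <- "A"
  cls[s > -0.07 & s <= -0.02] <- "B"
  cls[s > -0.02 & s <= -0.002] <- "C"
  cls[abs(s) < 0.002] <- "D"
  cls[s >= 0.002 & s < 0.02] <- "E"
  cls[s >= 0.02] <- "F"
  # boundary |1/L| == 0.002 belongs to D (|L| >= 500 is near-neutral)
  cls[abs(s) == 0.002] <- "D"
  cls
}

# Briggs rural (open-country) interpolation formulas, x in meters.
.briggs_rural <- list(
  A = list(sy = function(x) 0.22 * x / sqrt(1 + 0.0001 * x),
           sz = function(x) 0.20 * x),
  B = list(sy = function(x) 0.16 * x / sqrt(1 + 0.0001 * x),
           sz = function(x) 0.12 * x),
  C = list(sy = function(x) 0.11 * x / sqrt(1 + 0.0001 * x),
           sz = function(x) 0.08 * x / sqrt(1 + 0.0002 * x)),
  D = list(sy = function(x) 0.08 * x / sqrt(1 + 0.0001 * x),
           sz = function(x) 0.06 * x / sqrt(1 + 0.0015 * x)),
  E = list(sy = function(x) 0.06 * x / sqrt(1 + 0.0001 * x),
           sz = function(x) 0.03 * x / (1 + 0.0003 * x)),
  F = list(sy = function(x) 0.04 * x / sqrt(1 + 0.0001 * x),
           sz = function(x) 0.016 * x / (1 + 0.0003 * x))
)

.sigma_schemes <- new.env(parent = emptyenv())
.sigma_schemes$briggs_rural <- function(x, met, params) {
  cls <- stability_class(met$L)
  f <- .briggs_rural[[cls]]
  list(sy = f$sy(x), sz = f$sz(x))
}

#' Register a plume-spread scheme
#'
#' A scheme is a function `f(x, met, params)` returning `list(sy=, sz=)` for
#' a vector/matrix of downwind distances `x` (m) and one met record; it must
#' be positive and strictly increasing in x. This is the hook for swapping
#' in micrometeorology-based spread curves.
#'
#' @param name scheme name used in [dispersion_params()].
#' @param fn the scheme function.
#' @export
register_sigma_scheme <- function(name, fn) {
  stopifnot(is.function(fn))
  assign(name, fn, envir = .sigma_schemes)
  invisible(name)
}

.get_sigma_scheme <- function(params) {
  fn <- get0(params$sigma_scheme, envir = .sigma_schemes)
  if (is.null(fn)) stop("unknown sigma scheme: ", params$sigma_scheme)
  fn
}

#' Horizontal and vertical plume spread at a downwind distance
#'
#' @param x downwind distance m, > 0 (vectorised).
#' @param met one met record (a 1-row `surface_met` or list with `L`).
#' @param params [dispersion_params()].
#' @return `sigma_y`/`sigma_z`: numeric, m. The effective vertical spread
#'   used by the kernels is `sqrt(sigma_z(x)^2 + sigma_z0^2)`.
#' @export
sigma_y <- function(x, met, params = dispersion_params()) {
  if (any(x <= 0)) stop("sigma_y: downwind distance must be > 0")
  .get_sigma_scheme(params)(x, met, params)$sy
}

#' @rdname sigma_y
#' @export
sigma_z <- function(x, met, params = dispersion_params()) {
  if (any(x <= 0)) stop("sigma_z: downwind distance must be > 0")
  .get_sigma_scheme(params)(x, met, params)$sz
}
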