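#' Variogram model
#'
#' Isotropic semivariogram `gamma(h) = nugget + psill * g(h/range)` with
#' `g` the unit correlation-complement of the chosen family (exponential:
#' `1 - exp(-h/range)`; spherical; gaussian). The total sill is
#' `nugget + psill`.
#'
#' @param family `"exponential"`, `"spherical"` or `"gaussian"`.
#' @param nugget nugget variance, >= 0.
#' @param psill partial sill, > 0 (0 allowed only for the degenerate
#'   pure-nugget model).
#' @param range range parameter m, > 0.
#' @return object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "spherical", "gaussian"),
                            nugget, psill, range) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range), class = "variogram_model")
}

# unit structure function: 0 at h=0, -> 1 as h -> infinity
.vgm_g <- function(family, hr) {
  switch(family,
         exponential = 1 - exp(-hr),
         gaussian = 1 - exp(-hr^2),
         spherical = ifelse(hr >= 1, 1, 1.5 * hr - 0.5 * hr^3))
}

#' Evaluate a variogram model
#'
#' @param v a [variogram_model()].
#' @param h lag distances m (vectorised). `vgm_gamma(v, 0)` equals the
#'   nugget.
#' @return semivariance (`vgm_gamma`) or covariance (`vgm_cov`; at `h = 0`
#'   the covariance is the total sill, for `h > 0` the nugget is
#'   discontinuous).
#' @export
vgm_gamma <- function(v, h) v$nugget + v$psill * .vgm_g(v$family, h / v$range)

#' @rdname vgm_gamma
#' @export
vgm_cov <- function(v, h) {
  ifelse(h == 0, v$nugget + v$psill,
         v$psill * (1 - .vgm_g(v$family, h / v$range)))
}

#' Empirical (method-of-moments) semivariogram
#'
#' `gamma_hat(bin) = sum (z_i - z_j)^2 / (2 N_bin)` over point pairs whose
#' separation falls in the bin.
#'
#' @param x,y point coordinates m.
#' @param values values at the points.
#' @param n_bins number of lag bins (default 15); ignored when `breaks` is
#'   given.
#' @param max_lag largest lag considered (default 0.45 of the maximum pair
#'   distance).
#' @param breaks optional explicit bin breaks.
#' @return data frame `lag` (bin centers), `gamma`, `n_pairs`; empty bins
#'   are reported with `n_pairs = 0` and `gamma = NA`.
#' @export
empirical_semivariogram <- function(x, y, values, n_bins = 15, max_lag = NULL,
                                    breaks = NULL) {
  stopifnot(length(x) >= 2, length(x) == length(y), length(x) == length(values))
  d <- as.numeric(stats::dist(cbind(x, y)))
  g <- as.numeric(stats::dist(values))^2 / 2
  if (is.null(breaks)) {
    stopifnot(n_bins > 0)
    if (is.null(max_lag)) max_lag <- 0.45 * max(d)
    breaks <- seq(0, max_lag, length.out = n_bins + 1)
  }
  keep <- d <= max(breaks) & d > min(breaks)
  bin <- cut(d[keep], breaks, labels = FALSE)
  n_pairs <- tabulate(bin, nbins = length(breaks) - 1)
  gsum <- rep(0, length(breaks) - 1)
  tt <- tapply(g[keep], bin, sum)
  gsum[as.integer(names(tt))] <- tt
  data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
             gamma = ifelse(n_pairs > 0, gsum / n_pairs, NA),
             n_pairs = n_pairs)
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with weights equal to the pair counts, bounds
#' `nugget >= 0`, `psill > 0`, `range > 0`, minimised by L-BFGS-B from a
#' fixed multi-start grid (deterministic).
#'
#' @param emp data frame from [empirical_semivariogram()].
#' @param family variogram family (default exponential).
#' @return a [variogram_model()]. If every empirical value is 0 the
#'   degenerate pure-nugget-zero model is returned with a warning.
#' @export
fit_variogram <- function(emp, family = "exponential") {
  emp <- emp[emp$n_pairs > 0 & !is.na(emp$gamma), , drop = FALSE]
  if (nrow(emp) < 3) stop("fit_variogram: need >= 3 non-empty lag bins")
  if (all(emp$gamma == 0)) {
    warning("fit_variogram: all empirical semivariances are zero; ",
            "returning a degenerate pure-nugget model")
    return(variogram_model(family, nugget = 0, psill = 0,
                           range = max(emp$lag)))
  }
  h <- emp$lag; gh <- emp$gamma; wt <- emp$n_pairs
  obj <- function(par) {
    v <- list(family = family, nugget = par[1], psill = par[2], range = par[3])
    sum(wt * (gh - (v$nugget + v$psill * .vgm_g(family, h / v$range)))^2)
  }
  gmax <- max(gh)
  starts <- expand.grid(n = c(0, 0.25, 0.5) * gmax,
                        s = c(0.5, 1) * gmax,
                        r = c(0.1, 0.3, 0.7) * max(h))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                            lower = c(0, 1e-10 * gmax, 1e-6 * max(h)),
                            upper = c(2 * gmax, 4 * gmax, 20 * max(h))),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("fit_variogram: optimisation failed from every start")
  variogram_model(family, nugget = best$par[1], psill = best$par[2],
                  range = best$par[3])
}

#' Simple kriging with a known constant mean
#'
#' Predicts `mean + sum_i w_i (z_i - mean)` at each target, with weights
#' solving the simple-kriging system built from the covariance implied by
#' the variogram. The kriging variance `C(0) - w' c0` is returned alongside.
#'
#' @param x,y data coordinates m (distinct points).
#' @param values observed values.
#' @param mean the known (spatially constant) mean.
#' @param v a [variogram_model()].
#' @param tx,ty target coordinates.
#' @return list `pred`, `var` (numeric vectors over targets).
#' @export
simple_krige <- function(x, y, values, mean, v, tx, ty) {
  n <- length(x)
  stopifnot(length(y) == n, length(values) == n, length(tx) == length(ty))
  if (v$nugget + v$psill <= 0) {
    # degenerate (pure-zero) variogram: no spatial structure to use
    return(list(pred = rep(mean, length(tx)), var = rep(0, length(tx))))
  }
  D <- as.matrix(stats::dist(cbind(x, y)))
  dup <- which(D < 1e-9 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup)) {
    stop("simple_krige: duplicate data locations (rows ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "),
         "); the covariance matrix is singular")
  }
  C <- vgm_cov(v, D)
  sill <- v$nugget + v$psill
  d0 <- sqrt(outer(x, tx, "-")^2 + outer(y, ty, "-")^2)
  C0 <- vgm_cov(v, d0)
  W <- solve(C, C0)
  pred <- mean + as.numeric(crossprod(W, values - mean))
  var <- pmax(sill - colSums(W * C0), 0)
  list(pred = pred, var = var)
}

#' Regular map grid specification
#'
#' Node-registered regular grid covering `[xmin, xmax] x [ymin, ymax]` at
#' `res` meter spacing.
#'
#' @param xmin,xmax,ymin,ymax extent, projected meters.
#' @param res grid resolution m (default 1000).
#' @return object of class `grid_spec` with node coordinate vectors `gx`,
#'   `gy`.
#' @export
grid_spec <- function(xmin, xmax, ymin, ymax, res = 1000) {
  stopifnot(res > 0, xmax > xmin, ymax > ymin)
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 res = res,
                 gx = seq(xmin, xmax, by = res),
                 gy = seq(ymin, ymax, by = res)),
            class = "grid_spec")
}

# assemble a kriged_field object; values/variance are nx x ny matrices
# (x indexes rows, y columns)
.kriged_field <- function(gs, values, variance = NULL, mean = NA_real_) {
  structure(list(gx = gs$gx, gy = gs$gy,
                 values = matrix(values, length(gs$gx), length(gs$gy)),
                 variance = if (!is.null(variance))
                   matrix(variance, length(gs$gx), length(gs$gy)),
                 mean = mean, res = gs$res),
            class = "kriged_field")
}

#' @export
print.kriged_field <- function(x, ...) {
  cat("Kriged/model field:", length(x$gx), "x", length(x$gy), "nodes at",
      x$res, "m; value range", paste(signif(range(x$values), 4), collapse = " - "),
      "\n")
  invisible(x)
}

#' Dispersion-model mean concentration field on a grid
#'
#' Treats every grid node as a receptor, builds the transfer matrix over the
#' (non-calm) met series and multiplies by the fitted category rates.
#'
#' @param sources list of source objects.
#' @param emissions an `emission_estimate` (or named rate vector, tons/day).
#' @param met `surface_met` table.
#' @param gs a [grid_spec()].
#' @param grouping optional category grouping.
#' @param params [dispersion_params()].
#' @param z receptor height for grid nodes m (default 2).
#' @return a `kriged_field` holding the modeled mean field (no variance).
#' @export
model_grid_field <- function(sources, emissions, met, gs, grouping = NULL,
                             params = dispersion_params(), z = 2) {
  rates <- if (inherits(emissions, "emission_estimate")) emissions$rates else emissions
  nodes <- expand.grid(x = gs$gx, y = gs$gy)
  rec <- receptors(id = sprintf("g%06d", seq_len(nrow(nodes))),
                   x = nodes$x, y = nodes$y, z = z)
  tm <- build_transfer_matrix(sources, rec, met, grouping = grouping,
                              params = params)
  vals <- as.numeric(tm$values[, names(rates), drop = FALSE] %*% rates)
  .kriged_field(gs, vals, mean = mean(vals))
}

# model field value at arbitrary points by bilinear interpolation
.field_at <- function(field, px, py) {
  gx <- field$gx; gy <- field$gy
  ix <- pmin(pmax(findInterval(px, gx), 1L), length(gx) - 1L)
  iy <- pmin(pmax(findInterval(py, gy), 1L), length(gy) - 1L)
  tx <- (px - gx[ix]) / (gx[ix + 1L] - gx[ix])
  ty <- (py - gy[iy]) / (gy[iy + 1L] - gy[iy])
  v <- field$values
  v[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    v[cbind(ix + 1L, iy)] * tx * (1 - ty) +
    v[cbind(ix, iy + 1L)] * (1 - tx) * ty +
    v[cbind(ix + 1L, iy + 1L)] * tx * ty
}

#' Simple-kriging concentration map of raw observations
#'
#' Interpolates the observations themselves with simple kriging, using the
#' arithmetic mean of the observations as the known mean (the purely
#' statistical map the residual-kriging map is compared against).
#'
#' @param rec receptor data frame.
#' @param c_obs observed concentrations.
#' @param gs a [grid_spec()].
#' @param family variogram family (default exponential).
#' @param v optional pre-fitted [variogram_model()]; fitted from the
#'   observations when NULL.
#' @return a `kriged_field`.
#' @export
simple_krige_map <- function(rec, c_obs, gs, family = "exponential", v = NULL) {
  if (is.null(v)) {
    v <- fit_variogram(empirical_semivariogram(rec$x, rec$y, c_obs), family)
  }
  nodes <- expand.grid(x = gs$gx, y = gs$gy)
  sk <- simple_krige(rec$x, rec$y, c_obs, mean(c_obs), v, nodes$x, nodes$y)
  .kriged_field(gs, sk$pred, sk$var, mean = mean(c_obs))
}

#' Residual-kriging concentration map
#'
#' The mapping method: residuals `observed - modeled` at the receptors are
#' interpolated by simple kriging with known mean 0 (they are least-squares
#' residuals) and added to the dispersion-model mean field on the grid.
#' Negative map values are floored at 0 (with the count reported), applied
#' last.
#'
#' @param model_field `kriged_field` from [model_grid_field()].
#' @param rec receptor data frame.
#' @param c_obs observed concentrations at the receptors.
#' @param family variogram family for the residual field.
#' @param model_at_receptors optional model values at the receptors;
#'   bilinearly interpolated from `model_field` when NULL.
#' @param v optional pre-fitted residual [variogram_model()].
#' @param floor_zero floor negative map values at 0 (default TRUE).
#' @return a `kriged_field`; attributes `n_floored` (count of floored
#'   nodes) and `residuals` (data frame receptor_id, observed, modeled,
#'   residual).
#' @export
residual_krige_map <- function(model_field, rec, c_obs,
                               family = "exponential",
                               model_at_receptors = NULL, v = NULL,
                               floor_zero = TRUE) {
  if (nrow(rec) < 3) stop("residual_krige_map: need >= 3 receptors to fit a variogram")
  if (is.null(model_at_receptors)) {
    model_at_receptors <- .field_at(model_field, rec$x, rec$y)
  }
  r <- c_obs - model_at_receptors
  if (is.null(v)) {
    v <- fit_variogram(empirical_semivariogram(rec$x, rec$y, r), family)
  }
  nodes <- expand.grid(x = model_field$gx, y = model_field$gy)
  sk <- simple_krige(rec$x, rec$y, r, 0, v, nodes$x, nodes$y)
  vals <- as.numeric(model_field$values) + sk$pred
  n_floored <- 0L
  if (floor_zero && any(vals < 0)) {
    n_floored <- sum(vals < 0)
    message("residual_krige_map: floored ", n_floored, " negative node(s) at 0")
    vals <- pmax(vals, 0)
  }
  out <- .kriged_field(list(gx = model_field$gx, gy = model_field$gy,
                            res = model_field$res),
                       vals, sk$var, mean = mean(vals))
  attr(out, "n_floored") <- n_floored
  attr(out, "residuals") <- data.frame(receptor_id = rec$id,
                                       observed = c_obs,
                                       modeled = model_at_receptors,
                                       residual = r)
  attr(out, "variogram") <- v
  out
}

#' Write a field as an ESRI ASCII grid
#'
#' @param field a `kriged_field`.
#' @param path output `.asc` path. A companion CSV of `(x, y, value)` is
#'   written when `csv = TRUE`.
#' @param csv also write `<path>.csv` (default FALSE).
#' @export
write_asc <- function(field, path, csv = FALSE) {
  nx <- length(field$gx); ny <- length(field$gy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nx), paste("nrows", ny),
               paste("xllcorner", field$gx[1] - field$res / 2),
               paste("yllcorner", field$gy[1] - field$res / 2),
               paste("cellsize", field$res),
               "NODATA_value -9999"), con)
  for (j in rev(seq_len(ny))) {  # north to south
    writeLines(paste(signif(field$values[, j], 7), collapse = " "), con)
  }
  if (csv) {
    nodes <- expand.grid(x = field$gx, y = field$gy)
    utils::write.csv(data.frame(nodes, value = as.numeric(field$values)),
                     paste0(path, ".csv"), row.names = FALSE)
  }
  invisible(path)
}
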