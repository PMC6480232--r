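#' Estimate category emission rates by non-negative least squares
#'
#' Fits observed period-averaged concentrations as a non-negative linear
#' combination of the category transfer coefficients:
#' `c_obs_i = sum_k E_k T[i,k] + eps_i`, minimising the residual sum of
#' squares subject to `E_k >= 0` (Lawson-Hanson active set). A
#' Karush-Kuhn-Tucker certificate is evaluated at the solution: for every
#' category either the rate is positive and its gradient is ~0, or the rate
#' is 0 and its gradient is non-negative (within `kkt_tol` on the gradient
#' normalised by `||T||`).
#'
#' @param T a `transfer_matrix` or plain numeric matrix (receptors x
#'   categories, ug/m^3 per ton/day).
#' @param c_obs observed concentrations ug/m^3, aligned with the rows of T.
#' @param kkt_tol tolerance for the KKT certificate (default 1e-8).
#' @return object of class `emission_estimate`: `rates` (named, tons/day),
#'   `fitted`, `residuals` (observed - fitted), `objective` (RSS),
#'   `kkt_ok`, `kkt_gradient`.
#' @export
nnls_fit <- function(T, c_obs, kkt_tol = 1e-8) {
  A <- .tm_values(T)
  if (is.null(colnames(A))) colnames(A) <- paste0("cat", seq_len(ncol(A)))
  stopifnot(nrow(A) == length(c_obs))
  if (nrow(A) < ncol(A)) {
    warning("nnls_fit: fewer receptors (", nrow(A), ") than categories (",
            ncol(A), "); the fit is underdetermined")
  }
  zero_col <- colSums(abs(A)) == 0
  if (any(zero_col)) {
    warning("nnls_fit: transfer column(s) identically zero (rate forced to 0): ",
            paste(colnames(A)[zero_col], collapse = ", "))
  }
  E <- pracma::lsqnonneg(A, as.numeric(c_obs))$x
  names(E) <- colnames(A)
  fitted <- as.numeric(A %*% E)
  res <- as.numeric(c_obs) - fitted
  grad <- as.numeric(crossprod(A, fitted - as.numeric(c_obs)))
  scale <- max(colSums(A^2), .Machine$double.eps)
  gn <- grad / scale
  kkt_ok <- all(ifelse(E > 0, abs(gn) <= kkt_tol, gn >= -kkt_tol))
  structure(list(rates = E, fitted = fitted, residuals = res,
                 objective = sum(res^2), kkt_ok = kkt_ok,
                 kkt_gradient = gn),
            class = "emission_estimate")
}

#' @export
print.emission_estimate <- function(x, ...) {
  cat("Emission rates (tons/day):\n")
  print(round(x$rates, 3))
  cat("RSS:", signif(x$objective, 4), " KKT:", x$kkt_ok, "\n")
  invisible(x)
}

#' Residual-bootstrap confidence intervals for emission rates
#'
#' Residuals of the point fit are resampled with replacement across
#' receptors, added to the fitted concentrations to form pseudo-observations
#' (clipped at 0: concentrations cannot be negative), and refitted; the 95%
#' interval is the 2.5 and 97.5 percentile of the replicate distribution.
#'
#' @inheritParams nnls_fit
#' @param B number of bootstrap replicates (default 1000, must be >= 2).
#' @param seed RNG seed for reproducibility (the caller's RNG stream is
#'   left untouched).
#' @param probs CI percentiles (default `c(0.025, 0.975)`).
#' @return object of class `bootstrap_result`: `B`, `replicates` (B x K
#'   matrix), `ci` (data frame category, rate, ci_low, ci_high,
#'   ci_range_normalized), `seed`.
#' @export
bootstrap_ci <- function(T, c_obs, B = 1000, seed = NULL,
                         probs = c(0.025, 0.975)) {
  if (B < 2) stop("bootstrap_ci: B must be >= 2")
  A <- .tm_values(T)
  point <- nnls_fit(A, c_obs)
  n <- length(c_obs)
  reps <- .with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      pseudo <- pmax(point$fitted + sample(point$residuals, n, replace = TRUE), 0)
      suppressWarnings(nnls_fit(A, pseudo)$rates)
    }, numeric(ncol(A))))
  })
  colnames(reps) <- colnames(A)
  qs <- apply(reps, 2, stats::quantile, probs = probs, names = FALSE)
  ci <- data.frame(category = colnames(A), rate = unname(point$rates),
                   ci_low = qs[1, ], ci_high = qs[2, ])
  ci$ci_range_normalized <- ifelse(ci$rate > 0,
                                   (ci$ci_high - ci$ci_low) / ci$rate, NA)
  rownames(ci) <- NULL
  structure(list(B = B, replicates = reps, ci = ci, seed = seed,
                 point = point),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Residual bootstrap,", x$B, "replicates\n")
  print(transform(x$ci, rate = round(rate, 2), ci_low = round(ci_low, 2),
                  ci_high = round(ci_high, 2),
                  ci_range_normalized = round(ci_range_normalized, 2)))
  invisible(x)
}

#' Pooled fit across several averaging periods
#'
#' Stacks the per-period systems (rows concatenated) and fits a single set
#' of rates, i.e. assumes the emission rates do not vary across periods.
#'
#' @param T_list list of transfer matrices (or plain matrices), one per
#'   period.
#' @param c_list list of observation vectors aligned with `T_list`.
#' @inheritParams nnls_fit
#' @return an `emission_estimate` for the stacked system.
#' @export
fit_pooled <- function(T_list, c_list, kkt_tol = 1e-8) {
  if (length(T_list) != length(c_list)) {
    stop("fit_pooled: T_list and c_list must have the same length")
  }
  mats <- lapply(T_list, .tm_values)
  nc <- vapply(mats, ncol, integer(1))
  if (length(unique(nc)) != 1L) stop("fit_pooled: periods have differing categories")
  for (i in seq_along(mats)) {
    if (nrow(mats[[i]]) != length(c_list[[i]])) {
      stop("fit_pooled: period ", i, " misaligned: ", nrow(mats[[i]]),
           " receptors vs ", length(c_list[[i]]), " observations")
    }
  }
  nnls_fit(do.call(rbind, mats), unlist(c_list), kkt_tol = kkt_tol)
}

#' Independent fits per averaging period
#'
#' @inheritParams fit_pooled
#' @return list of `emission_estimate`, one per period.
#' @export
fit_per_period <- function(T_list, c_list, kkt_tol = 1e-8) {
  if (length(T_list) != length(c_list)) {
    stop("fit_per_period: T_list and c_list must have the same length")
  }
  lapply(seq_along(T_list), function(i) {
    nnls_fit(T_list[[i]], c_list[[i]], kkt_tol = kkt_tol)
  })
}

#' Sensitivity of fitted rates to the initial vertical plume spread
#'
#' Rebuilds the border line-source transfer columns for each candidate
#' `sigma_z0`, refits the emission rates against the same observations, and
#' tabulates rates per `sigma_z0`. Area sources keep their configured
#' spread.
#'
#' @param sources list of source objects; line sources get each swept
#'   `sigma_z0` in turn.
#' @param rec receptor data frame.
#' @param met `surface_met` table.
#' @param c_obs observed concentrations ug/m^3.
#' @param sigma_z0_values numeric vector of spreads m, >= 0.
#' @param grouping optional grouping (default length-proportional).
#' @param params [dispersion_params()].
#' @return list with `table` (data frame sigma_z0 x category rates),
#'   `fits` (list of `emission_estimate`), `transfer` (list of
#'   `transfer_matrix`).
#' @export
sigma_z0_sweep <- function(sources, rec, met, c_obs, sigma_z0_values,
                           grouping = NULL, params = dispersion_params()) {
  stopifnot(all(sigma_z0_values >= 0))
  out <- lapply(sigma_z0_values, function(s0) {
    src2 <- lapply(sources, function(s) {
      if (s$type == "line") s$sigma_z0 <- s0
      s
    })
    tm <- build_transfer_matrix(src2, rec, met, grouping = grouping,
                                params = params)
    list(tm = tm, fit = nnls_fit(tm, c_obs))
  })
  rates <- t(vapply(out, function(o) o$fit$rates,
                    numeric(length(out[[1]]$fit$rates))))
  tab <- data.frame(sigma_z0 = sigma_z0_values, rates, check.names = FALSE)
  list(table = tab, fits = lapply(out, `[[`, "fit"),
       transfer = lapply(out, `[[`, "tm"))
}
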