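#' Fraction of pairs within a factor f
#'
#' Fraction of receptor pairs whose modeled/observed ratio lies in
#' `[1/f, f]` (inclusive bounds); `f = 2` gives the usual FAC2 statistic.
#' Symmetric in observed and modeled.
#'
#' @param obs,mod strictly positive aligned vectors.
#' @param f factor (default 2).
#' @return fraction in `[0, 1]`.
#' @export
fraction_within_factor <- function(obs, mod, f = 2) {
  stopifnot(length(obs) == length(mod), f > 1)
  if (any(obs <= 0) || any(mod <= 0)) {
    stop("fraction_within_factor: values must be > 0 (ratio undefined)")
  }
  r <- mod / obs
  mean(r >= 1 / f & r <= f)
}

#' Geometric standard deviation of the observed-to-modeled ratio
#'
#' `sg = exp(sd(log(obs/mod)))` with the sample (n-1) standard deviation;
#' 1 means perfect agreement up to a constant factor, and the statistic is
#' invariant to a global rescaling of either vector.
#'
#' @param obs,mod strictly positive aligned vectors, n >= 2.
#' @return sg >= 1.
#' @export
geometric_sd_ratio <- function(obs, mod) {
  stopifnot(length(obs) == length(mod))
  if (length(obs) < 2) stop("geometric_sd_ratio: need n >= 2")
  if (any(obs <= 0) || any(mod <= 0)) {
    stop("geometric_sd_ratio: values must be > 0")
  }
  exp(stats::sd(log(obs / mod)))
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' @param obs,mod aligned vectors, n >= 2; the observed vector must have
#'   nonzero variance (a zero-variance vector leaves the statistic
#'   undefined, returned as NA with a warning).
#' @return r-squared in `[0, 1]`.
#' @export
r_squared <- function(obs, mod) {
  stopifnot(length(obs) == length(mod))
  if (length(obs) < 2) stop("r_squared: need n >= 2")
  if (stats::sd(obs) == 0 || stats::sd(mod) == 0) {
    warning("r_squared: undefined for zero-variance input")
    return(NA_real_)
  }
  stats::cor(obs, mod)^2
}

#' Model-performance report
#'
#' @param obs,mod aligned strictly positive vectors.
#' @param factors factors for the within-factor fractions (default 2 and
#'   1.5).
#' @return data frame with `n`, one `fraction_within_<f>` column per
#'   factor, `sg`, `r2`.
#' @export
performance_report <- function(obs, mod, factors = c(2, 1.5)) {
  out <- data.frame(n = length(obs))
  for (f in factors) {
    out[[paste0("fraction_within_", f)]] <- fraction_within_factor(obs, mod, f)
  }
  out$sg <- geometric_sd_ratio(obs, mod)
  out$r2 <- suppressWarnings(r_squared(obs, mod))
  out
}

#' Leave-one-out cross-validation: simple vs residual kriging
#'
#' Each receptor is held out in turn and predicted from the remaining ones
#' two ways: simple kriging of the raw observations (known mean = mean of
#' the remaining observations), and residual kriging (model value at the
#' held-out site + simple-kriged residual, mean 0). Variograms are fitted
#' once on the full data/residuals and held fixed across folds.
#'
#' @param rec receptor data frame (>= 4 rows).
#' @param c_obs observed concentrations.
#' @param model_at_receptors modeled concentrations at the receptors.
#' @param family variogram family (default exponential).
#' @param holdout_ids receptor ids to hold out (default all).
#' @param v_obs,v_res optional pre-fitted variogram models for the
#'   observation and residual fields.
#' @return list: `table` (data frame site, observed, pred_simple,
#'   pred_residual), `r2_simple`, `r2_residual`.
#' @export
loocv_compare <- function(rec, c_obs, model_at_receptors,
                          family = "exponential", holdout_ids = NULL,
                          v_obs = NULL, v_res = NULL) {
  if (nrow(rec) < 4) stop("loocv_compare: need >= 4 receptors")
  if (is.null(holdout_ids)) holdout_ids <- rec$id
  unknown <- setdiff(holdout_ids, rec$id)
  if (length(unknown)) stop("loocv_compare: unknown holdout id(s): ",
                            paste(unknown, collapse = ", "))
  resid <- c_obs - model_at_receptors
  if (is.null(v_obs)) {
    v_obs <- fit_variogram(empirical_semivariogram(rec$x, rec$y, c_obs), family)
  }
  if (is.null(v_res)) {
    v_res <- fit_variogram(empirical_semivariogram(rec$x, rec$y, resid), family)
  }
  rows <- lapply(holdout_ids, function(id) {
    i <- match(id, rec$id)
    ps <- simple_krige(rec$x[-i], rec$y[-i], c_obs[-i], mean(c_obs[-i]),
                       v_obs, rec$x[i], rec$y[i])$pred
    pr_res <- simple_krige(rec$x[-i], rec$y[-i], resid[-i], 0,
                           v_res, rec$x[i], rec$y[i])$pred
    data.frame(site = id, observed = c_obs[i], pred_simple = ps,
               pred_residual = model_at_receptors[i] + pr_res)
  })
  tab <- do.call(rbind, rows)
  r2_of <- function(p) {
    if (nrow(tab) < 2) return(NA_real_)
    suppressWarnings(r_squared(tab$observed, p))
  }
  list(table = tab,
       r2_simple = r2_of(tab$pred_simple),
       r2_residual = r2_of(tab$pred_residual))
}
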