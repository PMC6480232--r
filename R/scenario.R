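# Synthetic "valley" scenarios with the structure the pipeline assumes:
# a roughly 40 x 80 km agricultural valley bordered by desert line sources
# (west, east), a drying lake edge to the northwest, an international border
# to the south, the valley itself as an area source, a westerly-dominated
# wind climate with a day/night stability cycle, and a sparse receptor
# network biased toward populated clusters.

#' Generate an hourly meteorology series with a diurnal stability cycle
#'
#' Daytime hours are unstable (negative Monin-Obukhov length, deep mixed
#' layer, higher friction velocity), nighttime hours stable and weaker; a
#' prescribed fraction of hours is made calm (u* below the 0.1 m/s
#' threshold), placed preferentially at night. Wind direction is drawn from
#' a westerly-dominated mixture (predominant west and southwest sectors).
#'
#' @param n_hours number of hours, >= 1.
#' @param calm_frac fraction of hours below the calm threshold (default
#'   0.2); the calm count is exactly `round(calm_frac * n_hours)`.
#' @param seed RNG seed.
#' @param start first hour (ISO date, default "2017-01-01").
#' @return a `surface_met` table of `n_hours` records.
#' @export
generate_met_series <- function(n_hours, calm_frac = 0.2, seed = 1,
                                start = "2017-01-01") {
  stopifnot(n_hours >= 1, calm_frac >= 0, calm_frac < 1)
  .with_seed(seed, {
    ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
              by = "hour", length.out = n_hours)
    hod <- as.integer(format(ts, "%H"))
    day <- hod >= 8 & hod <= 18
    ustar <- ifelse(day,
                    pmax(exp(stats::rnorm(n_hours, log(0.35), 0.30)), 0.11),
                    pmax(exp(stats::rnorm(n_hours, log(0.18), 0.25)), 0.11))
    L <- ifelse(day,
                -exp(stats::runif(n_hours, log(15), log(300))),
                exp(stats::runif(n_hours, log(10), log(500))))
    zi <- ifelse(day, stats::runif(n_hours, 800, 1800),
                 stats::runif(n_hours, 100, 400))
    n_calm <- round(calm_frac * n_hours)
    if (n_calm > 0) {
      w <- ifelse(day, 1, 4)  # calms mostly at night
      calm_idx <- sample(n_hours, n_calm, prob = w)
      ustar[calm_idx] <- stats::runif(n_calm, 0.02, 0.095)
    }
    # westerly-dominated rose: W, SW, a minor E-SE sector, a minor N-NW
    # (winter) sector, plus a uniform remainder
    sector <- sample(5, n_hours, replace = TRUE,
                     prob = c(0.45, 0.22, 0.13, 0.10, 0.10))
    wdir <- ifelse(sector == 1, stats::rnorm(n_hours, 265, 25),
            ifelse(sector == 2, stats::rnorm(n_hours, 225, 20),
            ifelse(sector == 3, stats::rnorm(n_hours, 115, 35),
            ifelse(sector == 4, stats::rnorm(n_hours, 335, 25),
                   stats::runif(n_hours, 0, 360))))) %% 360
    # neutral-ish log profile from u*: u(10 m) with z0 ~ 5 cm, mild scatter
    u_ref <- ustar / 0.4 * log(10 / 0.05) * exp(stats::rnorm(n_hours, 0, 0.10))
    surface_met(format(ts, "%Y-%m-%dT%H:%M:%S"), u_ref = u_ref, wdir = wdir,
                ustar = ustar, L = L, zi = zi, z_ref = 10)
  })
}

#' Generate a complete synthetic valley scenario
#'
#' Builds the source set (11 border line sources in 4 categories + 1
#' interior area source), a receptor network clustered toward "populated"
#' areas, an hourly met series, and the true category emission rates. The
#' default true rates (tons/day) are of the magnitude reported for a
#' comparable real valley: West Desert 2.8, Salton Sea 3.5, East Desert
#' 0.34, Mexico 2.8, Valley 12.4. Deterministic given the seed.
#'
#' @param seed RNG seed (default 1).
#' @param n_receptors number of receptors (default 20).
#' @param n_hours hours of meteorology (default 900).
#' @param calm_frac fraction of calm hours (default 0.2; the default 900
#'   hours then leave 720 non-calm hours).
#' @param true_rates named vector of true category rates, tons/day.
#' @param domain `c(width_east_m, height_north_m)` (default 40 x 80 km).
#' @param sigma_z0_border initial vertical spread of border lines m
#'   (default 10).
#' @return list with `sources`, `receptors`, `met`, `E_true`, `grouping`,
#'   `domain`, `seed`.
#' @export
valley_scenario <- function(seed = 1, n_receptors = 20, n_hours = 900,
                            calm_frac = 0.2,
                            true_rates = c("West Desert" = 2.8,
                                           "Salton Sea" = 3.5,
                                           "East Desert" = 0.34,
                                           "Mexico" = 2.8,
                                           "Valley" = 12.4),
                            domain = c(40000, 80000),
                            sigma_z0_border = 10) {
  stopifnot(all(true_rates >= 0))
  W <- domain[1]; H <- domain[2]
  seg <- function(id, cat, x1, y1, x2, y2) {
    line_source(id, x1, y1, x2, y2, cat, sigma_z0 = sigma_z0_border)
  }
  sources <- list(
    # 3 western desert segments along the west edge
    seg("west1", "West Desert", 0, 0, 0, H / 3),
    seg("west2", "West Desert", 0, H / 3, 0, 2 * H / 3),
    seg("west3", "West Desert", 0, 2 * H / 3, 0, H),
    # exposed lakebed edge along the northwest top
    seg("salton1", "Salton Sea", 0, H, 0.55 * W, H),
    # 3 eastern desert segments along the east edge
    seg("east1", "East Desert", W, 0, W, H / 3),
    seg("east2", "East Desert", W, H / 3, W, 2 * H / 3),
    seg("east3", "East Desert", W, 2 * H / 3, W, H),
    # 4 segments along the southern international border
    seg("mex1", "Mexico", 0, 0, W / 4, 0),
    seg("mex2", "Mexico", W / 4, 0, W / 2, 0),
    seg("mex3", "Mexico", W / 2, 0, 3 * W / 4, 0),
    seg("mex4", "Mexico", 3 * W / 4, 0, W, 0),
    # the valley itself as one interior area source
    area_source("valley", c(0, W, W, 0), c(0, 0, H, H), "Valley",
                sigma_z0 = 0)
  )
  rec <- .with_seed(seed, {
    # "town" anchors emulating a community network: a southern border city
    # and corridor, west- and east-side towns, central and northern towns,
    # two near-shore sites below the northern lake edge, and a west-edge
    # community; extra receptors re-draw towns with population-like weights
    towns <- rbind(c(0.45, 0.05), c(0.45, 0.09), c(0.45, 0.15), c(0.47, 0.20),
                   c(0.30, 0.16), c(0.72, 0.15), c(0.90, 0.10),
                   c(0.45, 0.45), c(0.30, 0.52), c(0.55, 0.60),
                   c(0.62, 0.78), c(0.40, 0.88), c(0.60, 0.84),
                   c(0.12, 0.30))
    nt <- nrow(towns)
    k <- c(seq_len(min(nt, n_receptors)),
           if (n_receptors > nt)
             sample(nt, n_receptors - nt, replace = TRUE,
                    prob = c(2, 2, 3, 2, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1)))
    x <- pmin(pmax(towns[k, 1] * W + stats::rnorm(n_receptors, 0, 1500),
                   0.03 * W), 0.97 * W)
    y <- pmin(pmax(towns[k, 2] * H + stats::rnorm(n_receptors, 0, 1500),
                   0.03 * H), 0.97 * H)
    receptors(sprintf("r%02d", seq_len(n_receptors)), x, y, z = 2)
  })
  met <- generate_met_series(n_hours, calm_frac, seed = seed + 1L)
  list(sources = sources, receptors = rec, met = met,
       E_true = true_rates, grouping = default_grouping(sources),
       domain = domain, seed = seed)
}

#' Synthetic period-averaged observations from a transfer matrix
#'
#' `c_obs = (T E_true) * exp(N(0, noise_sd^2))`, optionally plus a spatially
#' correlated residual field drawn from a variogram model (to exercise
#' residual kriging), floored at 0. With `noise_sd = 0` and no residual
#' field the observations satisfy the linear model exactly.
#'
#' @param T `transfer_matrix` or matrix (receptors x categories).
#' @param E_true named true rates, tons/day.
#' @param noise_sd standard deviation of the multiplicative lognormal
#'   observation noise (default 0.15, typical relative scatter of low-cost
#'   optical sensors at monthly averaging).
#' @param rec receptor data frame; required when `resid_vgm` is given.
#' @param resid_vgm optional [variogram_model()] for an additive spatially
#'   correlated error field, ug/m^3.
#' @param seed RNG seed.
#' @return numeric vector of observations, ug/m^3.
#' @export
make_observations <- function(T, E_true, noise_sd = 0.15, rec = NULL,
                              resid_vgm = NULL, seed = NULL) {
  A <- .tm_values(T)
  base <- as.numeric(A[, names(E_true), drop = FALSE] %*% E_true)
  .with_seed(seed, {
    out <- base
    if (noise_sd > 0) out <- out * exp(stats::rnorm(length(out), 0, noise_sd))
    if (!is.null(resid_vgm)) {
      stopifnot(!is.null(rec))
      D <- as.matrix(stats::dist(cbind(rec$x, rec$y)))
      C <- vgm_cov(resid_vgm, D)
      out <- out + as.numeric(crossprod(chol(C), stats::rnorm(nrow(D))))
    }
    pmax(out, 0)
  })
}
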