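# lenient ISO-8601 hour parser: unmatched strings give NA, never an error
.parse_hour <- function(x) {
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (f in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(as.character(x[miss]), format = f, tz = "UTC")
  }
  out
}

#' Read an hourly surface meteorology table
#'
#' Reads a delimited file of hourly dispersion meteorology. Required columns
#' (any order, matched by header name): `timestamp` (ISO-8601 hour), `u_ref`
#' (wind speed m/s at `z_ref`), `z_ref` (m), `wdir` (degrees, meteorological
#' convention: direction the wind blows FROM, clockwise from north), `ustar`
#' (friction velocity m/s), `L` (Monin-Obukhov length m, signed, never 0),
#' `zi` (mixing height m).
#'
#' Rows violating the physical invariants (`u_ref >= 0`, `0 <= wdir < 360`,
#' `ustar > 0`, `zi > 0`, `|L| > 0`) or with unparseable timestamps are
#' dropped with a message listing the offending row numbers.
#'
#' @param path path to a CSV file with the columns above.
#' @return a `surface_met` data frame, rows in time order.
#' @export
read_surface_met <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("timestamp", "u_ref", "z_ref", "wdir", "ustar", "L", "zi")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("met file is missing required column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[required]
  ts <- .parse_hour(df$timestamp)
  bad_ts <- is.na(ts)
  num <- c("u_ref", "z_ref", "wdir", "ustar", "L", "zi")
  for (v in num) df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  bad_inv <- bad_ts |
    is.na(df$u_ref) | df$u_ref < 0 |
    is.na(df$wdir) | df$wdir < 0 | df$wdir >= 360 |
    is.na(df$ustar) | df$ustar <= 0 |
    is.na(df$zi) | df$zi <= 0 |
    is.na(df$L) | df$L == 0 |
    is.na(df$z_ref) | df$z_ref <= 0
  if (any(bad_inv)) {
    message("read_surface_met: dropped ", sum(bad_inv), " invalid row(s): ",
            paste(which(bad_inv), collapse = ", "))
    df <- df[!bad_inv, , drop = FALSE]
    ts <- ts[!bad_inv]
  }
  df <- df[order(ts), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("surface_met", "data.frame")
  df
}

#' Construct a surface meteorology table from vectors
#'
#' @param timestamp character or POSIXct hour stamps.
#' @param u_ref wind speed m/s at `z_ref`.
#' @param z_ref anemometer height m (default 10).
#' @param wdir wind direction, degrees FROM, clockwise from north.
#' @param ustar friction velocity m/s.
#' @param L Monin-Obukhov length m (signed, nonzero).
#' @param zi mixing height m.
#' @return a `surface_met` data frame.
#' @export
surface_met <- function(timestamp, u_ref, wdir, ustar, L, zi, z_ref = 10) {
  df <- data.frame(timestamp = as.character(timestamp), u_ref = u_ref,
                   z_ref = z_ref, wdir = wdir, ustar = ustar, L = L, zi = zi,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$u_ref >= 0), all(df$wdir >= 0 & df$wdir < 360),
            all(df$ustar > 0), all(df$zi > 0), all(df$L != 0))
  class(df) <- c("surface_met", "data.frame")
  df
}

#' Remove calm hours from a meteorology series
#'
#' Hours with friction velocity at or below `ustar_min` are treated as calm
#' and excluded: the steady-state plume model is not applicable to stagnant
#' conditions. The threshold is applied with strict inequality (the filter
#' keeps hours with u* strictly above the threshold).
#'
#' @param met a `surface_met` data frame.
#' @param ustar_min calm threshold, m/s (default 0.1).
#' @return the subset of rows with `ustar > ustar_min`, order preserved; the
#'   number of removed hours is reported with a message and attached as
#'   attribute `n_removed`.
#' @export
filter_calm <- function(met, ustar_min = 0.1) {
  stopifnot(ustar_min > 0)
  keep <- met$ustar > ustar_min
  out <- met[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_removed <- sum(!keep)
  message("filter_calm: removed ", n_removed, " calm hour(s) (u* <= ",
          ustar_min, " m/s), kept ", nrow(out))
  if (nrow(out) == 0L) warning("filter_calm: no hours remain after calm filter")
  attr(out, "n_removed") <- n_removed
  out
}

#' Transport direction unit vector from a meteorological wind direction
#'
#' Meteorological wind direction is the direction the wind blows FROM,
#' measured clockwise from north. The transport vector points where material
#' is carried TO, in map coordinates (x east, y north). A westerly wind
#' (270 degrees) transports toward the east: `c(1, 0)`.
#'
#' @param wdir wind direction in degrees, `0 <= wdir < 360`.
#' @return numeric length-2 unit vector `(ux, uy)`.
#' @export
wind_transport_vector <- function(wdir) {
  stopifnot(length(wdir) == 1L, wdir >= 0, wdir < 360)
  th <- wdir * pi / 180
  c(-sin(th), -cos(th))
}

#' Build per-sensor availability summaries from long-format observations
#'
#' @param obs data frame with columns `timestamp`, `receptor_id`, `pm25`
#'   (hourly; missing hours simply absent or NA).
#' @return list of `sensor_series` objects, one per receptor, each with the
#'   hours present per calendar month and the count of "operational" months
#'   (a month counts as operational when at least 75% of its hours have a
#'   non-missing value).
#' @export
sensor_series_from_obs <- function(obs) {
  stopifnot(all(c("timestamp", "receptor_id", "pm25") %in% names(obs)))
  ts <- .parse_hour(obs$timestamp)
  mon <- format(ts, "%Y-%m")
  present <- !is.na(obs$pm25)
  if (any(obs$pm25[present] < 0)) stop("pm25 values must be >= 0 where present")
  days_in_month <- function(ym) {
    start <- as.Date(paste0(ym, "-01"))
    as.integer(seq(start, by = "month", length.out = 2)[2] - start)
  }
  lapply(split(seq_len(nrow(obs)), obs$receptor_id), function(idx) {
    hpm <- tapply(present[idx], mon[idx], sum)
    hpm <- hpm[!is.na(hpm)]
    full <- vapply(names(hpm), function(ym) 24L * days_in_month(ym), integer(1))
    structure(list(
      receptor_id = obs$receptor_id[idx[1]],
      hours_per_month = as.list(hpm),
      months_operational = sum(hpm >= 0.75 * full)
    ), class = "sensor_series")
  })
}

#' Screen sensors by operational availability
#'
#' Annual mode keeps sensors operational for at least `min_months` months
#' (a month is operational when at least 75% of its hours are present).
#' Monthly mode keeps, separately for each month, the sensors with at least
#' `min_hours_per_month` hours of data in that month.
#'
#' @param series list of `sensor_series` (see [sensor_series_from_obs()]).
#' @param min_months minimum operational months for the annual screen
#'   (default 6).
#' @param min_hours_per_month minimum hours per month for the monthly screen
#'   (default 100).
#' @param mode `"annual"` or `"monthly"`.
#' @return annual mode: character vector of included receptor ids. Monthly
#'   mode: named list, month -> included receptor ids.
#' @export
screen_sensors <- function(series, min_months = 6, min_hours_per_month = 100,
                           mode = c("annual", "monthly")) {
  mode <- match.arg(mode)
  ids <- vapply(series, function(s) as.character(s$receptor_id), character(1))
  if (mode == "annual") {
    keep <- vapply(series, function(s) s$months_operational >= min_months, logical(1))
    if (!any(keep)) {
      stop("screen_sensors: the >= ", min_months,
           " operational months screen eliminated all sensors")
    }
    message("screen_sensors: kept ", sum(keep), "/", length(keep),
            " sensors (annual screen)")
    return(unname(ids[keep]))
  }
  months <- sort(unique(unlist(lapply(series, function(s) names(s$hours_per_month)))))
  out <- lapply(months, function(m) {
    keep <- vapply(series, function(s) {
      h <- s$hours_per_month[[m]]
      !is.null(h) && h >= min_hours_per_month
    }, logical(1))
    unname(ids[keep])
  })
  names(out) <- months
  if (all(lengths(out) == 0L)) {
    stop("screen_sensors: the >= ", min_hours_per_month,
         " hours/month screen eliminated all sensors in every month")
  }
  out
}
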