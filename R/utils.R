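#' @keywords internal
"_PACKAGE"

# grams per short ton (2000 lb); emission inventories for the region report
# short tons per day
.TON_G <- 907184.74
.SECONDS_PER_DAY <- 86400

#' Convert an emission rate from short tons per day to grams per second
#'
#' Emission rates are reported in short tons per day (the unit used by the
#' regional bottom-up inventories); dispersion kernels work in g/s.
#'
#' @param rate numeric vector of emission rates, tons/day; must be >= 0.
#' @return numeric vector, g/s.
#' @examples
#' tons_per_day_to_g_per_s(1)    # ~10.5 g/s
#' @export
tons_per_day_to_g_per_s <- function(rate) {
  stopifnot(is.numeric(rate))
  if (any(rate < 0, na.rm = TRUE)) {
    stop("emission rates must be non-negative (tons/day)")
  }
  rate * .TON_G / .SECONDS_PER_DAY
}

# microgram/m^3 per (ton/day) given a coupling in s/m^3:
# coupling [s/m^3] * rate [g/s] = g/m^3; * 1e6 -> ug/m^3
.coupling_to_ug_per_tpd <- function(coupling) {
  coupling * tons_per_day_to_g_per_s(1) * 1e6
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the stream untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Shoelace area of a simple polygon (absolute value).
.polygon_area <- function(px, py) {
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  abs(sum(px[j] * py - px * py[j])) / 2
}

# Ray-casting point-in-polygon test, vectorised over query points.
.point_in_polygon <- function(qx, qy, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(qx))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > qy) != (py[j] > qy)) &
      (qx < (px[j] - px[i]) * (qy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}
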