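# Steady-state Gaussian plume kernels. All couplings are concentrations per
# unit emission rate (s/m^3): multiply by a source strength in g/s to get
# g/m^3. Geometry is planar projected meters, x east, y north; internally
# everything is rotated into the wind frame (transport along +x).

# rotate map coordinates into the wind frame for one met record:
# along-wind coordinate increases in the transport direction
.wind_frame <- function(x, y, wdir) {
  tv <- wind_transport_vector(wdir)
  list(a = x * tv[1] + y * tv[2], c = -x * tv[2] + y * tv[1])
}

# Vertical distribution factor with full ground reflection and n_reflections
# pairs of mixing-lid images; switches to the well-mixed limit 1/zi when the
# effective spread exceeds mixed_limit_factor * zi. All args vectorised.
.vertical_term <- function(sz_eff, zr, h, zi, params) {
  V <- 0
  for (n in -params$n_reflections:params$n_reflections) {
    V <- V + stats::dnorm(zr, mean = 2 * n * zi + h, sd = sz_eff) +
      stats::dnorm(zr, mean = 2 * n * zi - h, sd = sz_eff)
  }
  mixed <- sz_eff > params$mixed_limit_factor * zi
  if (any(mixed)) V[mixed] <- 1 / zi
  V
}

# Core kernel on wind-frame offsets. dx = along-wind receptor-minus-source
# distance, dy = crosswind offset; h source height(s); zr receptor height(s).
# Shapes of dx/dy (vector or matrix) are preserved; h, zr recycle.
.point_kernel_core <- function(dx, dy, zr, h, sigma_z0, met, params) {
  out <- dx * 0
  ok <- dx >= params$min_downwind
  if (!any(ok)) return(out)
  x <- dx[ok]
  sig <- .get_sigma_scheme(params)(x, met, params)
  sz_eff <- sqrt(sig$sz^2 + sigma_z0^2)
  fy <- stats::dnorm(dy[ok], mean = 0, sd = sig$sy)
  hh <- if (length(h) == 1L) h else rep(h, length.out = length(dx))[ok]
  zz <- if (length(zr) == 1L) zr else rep(zr, length.out = length(dx))[ok]
  V <- .vertical_term(sz_eff, zz, hh, met$zi, params)
  out[ok] <- fy * V / met$u_ref
  out
}

#' Gaussian plume point-source kernel
#'
#' Concentration per unit emission rate (s/m^3) from one or more point
#' sources at a receptor, with full ground reflection and mixing-lid image
#' pairs; contributions from sources closer than `min_downwind` along-wind
#' (including all upwind sources) are zero. The transport speed is the
#' reference wind speed `u_ref` of the met record.
#'
#' @param src either `c(x, y, h)` for a single point or a data frame with
#'   columns `x`, `y` and optionally `h` (default 0) for many points.
#' @param rec single receptor: list or 1-row data frame with `x`, `y`, `z`.
#' @param met one met record (1-row `surface_met` or list).
#' @param params [dispersion_params()].
#' @param sigma_z0 initial vertical spread m added in quadrature to
#'   `sigma_z(x)` (default 0).
#' @return numeric vector of couplings, one per source point.
#' @export
point_kernel <- function(src, rec, met, params = dispersion_params(),
                         sigma_z0 = 0) {
  if (is.numeric(src) && is.null(dim(src))) {
    stopifnot(length(src) %in% 2:3)
    src <- data.frame(x = src[1], y = src[2], h = if (length(src) == 3) src[3] else 0)
  }
  src <- as.data.frame(src)
  if (!"h" %in% names(src)) src$h <- 0
  sf <- .wind_frame(src$x, src$y, met$wdir)
  rf <- .wind_frame(rec$x[1], rec$y[1], met$wdir)
  .point_kernel_core(rf$a - sf$a, rf$c - sf$c, zr = rec$z[1], h = src$h,
                     sigma_z0 = sigma_z0, met = met, params = params)
}

# Line integral of the point kernel along a finite line source at arbitrary
# wind angle, refined by doubling the number of integration points until the
# relative change at every receptor is below line_tol. Integration points
# are log-spaced in the along-wind distance from each receptor (the kernel's
# scales sigma_y, sigma_z all grow with that distance, so the integrand is
# smooth on a log axis even for near-parallel winds). A line perpendicular
# to the wind is a single crosswind slice whose integral is exact. Returns
# coupling per unit TOTAL line emission rate for each receptor.
.line_coupling_multi <- function(line, rx, ry, rz, met, params) {
  len <- .line_length(line)
  rf <- .wind_frame(rx, ry, met$wdir)
  R <- length(rx)
  if (len < 1e-9) {
    sf <- .wind_frame(line$x1, line$y1, met$wdir)
    return(.point_kernel_core(rf$a - sf$a, rf$c - sf$c, rz, line$h,
                              line$sigma_z0, met, params))
  }
  e1 <- .wind_frame(line$x1, line$y1, met$wdir)
  e2 <- .wind_frame(line$x2, line$y2, met$wdir)
  da <- e2$a - e1$a
  est <- numeric(R)
  if (abs(da) <= 1e-9 * len) {
    # crosswind line: the along-line integral is a Gaussian CDF difference
    xp <- rf$a - (e1$a + e2$a) / 2
    ok <- xp >= params$min_downwind
    if (any(ok)) {
      x <- xp[ok]
      sig <- .get_sigma_scheme(params)(x, met, params)
      sz_eff <- sqrt(sig$sz^2 + line$sigma_z0^2)
      clo <- min(e1$c, e2$c); chi <- max(e1$c, e2$c)
      Iy <- stats::pnorm((rf$c[ok] - clo) / sig$sy) -
        stats::pnorm((rf$c[ok] - chi) / sig$sy)
      zz <- if (length(rz) == 1L) rz else rz[ok]
      V <- .vertical_term(sz_eff, zz, line$h, met$zi, params)
      est[ok] <- Iy * V / (met$u_ref * len)
    }
    return(est)
  }
  a_min <- min(e1$a, e2$a); a_max <- max(e1$a, e2$a)
  lo <- pmax(params$min_downwind, rf$a - a_max)
  hi <- rf$a - a_min
  act <- which(hi > lo)
  if (!length(act)) return(est)
  rza <- if (length(rz) == 1L) rep(rz, R) else rz
  # Two log-graded half-meshes over the downwind-distance window [lo, hi]:
  # one refined toward the receptor (near-field growth of the kernel), one
  # toward the line's upwind end (where the scaled crosswind offset can
  # reach its minimum, concentrating the integrand at that boundary).
  # 2-point Gauss-Legendre nodes within each cell; the cell count doubles
  # until each receptor's value is converged, and converged receptors drop
  # out of further refinement.
  w0 <- params$min_downwind
  gl <- 0.5 / sqrt(3)
  quad <- function(idx, nh) {
    Ra <- length(idx)
    m <- 2L * nh
    xmi <- sqrt(lo[idx] * hi[idx])
    t1lo <- log(lo[idx]); dt1 <- (log(xmi) - t1lo) / nh
    t2lo <- log(w0); dt2 <- (log(hi[idx] - xmi + w0) - t2lo) / nh
    k <- rep.int(c(seq_len(nh) - 0.5 - gl, seq_len(nh) - 0.5 + gl), Ra)
    x1 <- exp(rep(t1lo, each = m) + k * rep(dt1, each = m))
    wv <- exp(t2lo + k * rep(dt2, each = m))
    x2 <- rep(hi[idx], each = m) + w0 - wv
    xp <- c(x1, x2)
    jac <- c(x1 * rep(dt1, each = m), wv * rep(dt2, each = m)) / 2
    ra <- rep.int(rep(rf$a[idx], each = m), 2)
    rc <- rep.int(rep(rf$c[idx], each = m), 2)
    a_p <- ra - xp
    c_p <- e1$c + (a_p - e1$a) / da * (e2$c - e1$c)
    K <- .point_kernel_core(xp, rc - c_p,
                            zr = rep.int(rep(rza[idx], each = m), 2),
                            h = line$h, sigma_z0 = line$sigma_z0,
                            met = met, params = params)
    contrib <- K * jac
    dim(contrib) <- c(m, 2L * Ra)
    sums <- colSums(contrib)
    (sums[seq_len(Ra)] + sums[Ra + seq_len(Ra)]) / abs(da)
  }
  active <- act
  nh <- 8L
  prev <- quad(active, nh)
  gmax <- max(abs(prev), 1e-300)
  for (lev in seq_len(params$max_doublings)) {
    nh <- nh * 2L
    cur <- quad(active, nh)
    gmax <- max(gmax, abs(cur))
    conv <- abs(cur - prev) <= params$line_tol * abs(cur) + 1e-9 * gmax
    est[active[conv]] <- cur[conv]
    active <- active[!conv]
    if (!length(active)) return(est)
    prev <- cur[!conv]
  }
  stop("line_source_coupling: integral did not converge after ",
       params$max_doublings, " doublings for ", length(active),
       " receptor(s); last two iterates (max): ",
       signif(max(abs(prev)), 6), " -> ", signif(max(abs(cur)), 6))
}

#' Coupling of a finite line source at a receptor
#'
#' Mean of the point kernel along the line (equivalently `1/L * integral`),
#' i.e. the concentration per unit TOTAL line emission rate (s/m^3), with the
#' line's total emission spread uniformly along its length. The integral is
#' evaluated by midpoint-rule refinement, doubling the number of integration
#' points until the relative change is below `params$line_tol`; the wind may
#' be at any angle to the line.
#'
#' @param line a [line_source()].
#' @param rec receptor data frame (one or more rows with `x`, `y`, `z`).
#' @inheritParams point_kernel
#' @return numeric vector, one coupling per receptor row.
#' @export
line_source_coupling <- function(line, rec, met, params = dispersion_params()) {
  .line_coupling_multi(line, rec$x, rec$y, rec$z, met, params)
}

# Scanline slicing: y-intervals of the (wind-frame) polygon cut by vertical
# lines at xs. Half-open edge test gives an even crossing count per slice.
# Returns parallel vectors: slice index, lower y, upper y.
.slice_intervals <- function(px, py, xs) {
  n <- length(px)
  jj <- c(n, seq_len(n - 1))
  sl <- integer(0); yv <- numeric(0)
  for (e in seq_len(n)) {
    x1 <- px[jj[e]]; y1 <- py[jj[e]]; x2 <- px[e]; y2 <- py[e]
    m <- (x1 > xs) != (x2 > xs)
    if (any(m)) {
      t <- (xs[m] - x1) / (x2 - x1)
      sl <- c(sl, which(m))
      yv <- c(yv, y1 + t * (y2 - y1))
    }
  }
  o <- order(sl, yv)
  sl <- sl[o]; yv <- yv[o]
  r <- sequence(rle(sl)$lengths)
  list(slice = sl[r %% 2L == 1L], y1 = yv[r %% 2L == 1L], y2 = yv[r %% 2L == 0L])
}

# Area-source coupling by decomposition into crosswind line sources
# (slices perpendicular to the wind); within a slice the crosswind Gaussian
# integral is exact (normal CDF differences), and the slice count is doubled
# until the relative change at every receptor is below area_tol. Slices are
# placed log-spaced in the upwind distance from each receptor (the integrand
# varies on the scale of that distance), so the near-field peak and the
# long 1/x tail are both resolved with modest slice counts.
.area_coupling_multi <- function(area, rx, ry, rz, met, params) {
  pf <- .wind_frame(area$px, area$py, met$wdir)
  rf <- .wind_frame(rx, ry, met$wdir)
  A <- .polygon_area(area$px, area$py)
  xmin <- min(pf$a); xmax <- max(pf$a)
  R <- length(rx)
  est <- numeric(R)
  # upwind-distance integration window per receptor, clipped to the
  # polygon's along-wind extent
  lo <- pmax(params$min_downwind, rf$a - xmax)
  hi <- rf$a - xmin
  act <- which(hi > lo)
  if (!length(act)) return(est)
  rza <- if (length(rz) == 1L) rep(rz, length(rx)) else rz
  quad <- function(idx, n) {
    Ra <- length(idx)
    tlo <- log(lo[idx]); dt <- (log(hi[idx]) - tlo) / n
    # n x Ra matrix of log-distance midpoints, flattened column-major
    tt <- rep(tlo, each = n) + (rep.int(seq_len(n), Ra) - 0.5) * rep(dt, each = n)
    xp <- exp(tt)                                 # upwind distance of slice
    xs <- rep(rf$a[idx], each = n) - xp           # slice along-wind position
    iv <- .slice_intervals(pf$a, pf$c, xs)
    cur <- numeric(Ra)
    if (length(iv$slice)) {
      col <- (iv$slice - 1L) %/% n + 1L           # receptor index (into idx)
      x <- xp[iv$slice]
      sig <- .get_sigma_scheme(params)(x, met, params)
      sz_eff <- sqrt(sig$sz^2 + area$sigma_z0^2)
      cr <- rf$c[idx][col]
      Iy <- stats::pnorm((cr - iv$y1) / sig$sy) -
        stats::pnorm((cr - iv$y2) / sig$sy)
      V <- .vertical_term(sz_eff, rza[idx][col], area$h, met$zi, params)
      contrib <- x * dt[col] * Iy * V / met$u_ref  # x = log-space Jacobian
      s <- rowsum(contrib, col, reorder = FALSE)
      cur[as.integer(rownames(s))] <- s
    }
    cur / A
  }
  active <- act
  n <- 16L
  prev <- quad(active, n)
  gmax <- max(abs(prev), 1e-300)
  for (lev in seq_len(params$max_doublings)) {
    n <- n * 2L
    cur <- quad(active, n)
    gmax <- max(gmax, abs(cur))
    # relative convergence with a negligible-coupling floor (see line case)
    conv <- abs(cur - prev) <= params$area_tol * abs(cur) + 1e-9 * gmax
    est[active[conv]] <- cur[conv]
    active <- active[!conv]
    if (!length(active)) return(est)
    prev <- cur[!conv]
  }
  stop("area_source_coupling: slice decomposition did not converge after ",
       params$max_doublings, " doublings for ", length(active),
       " receptor(s); last two iterates (max): ",
       signif(max(abs(prev)), 6), " -> ", signif(max(abs(cur)), 6))
}

#' Coupling of a polygonal area source at a receptor
#'
#' The polygon is decomposed into line sources perpendicular to the wind;
#' only slices upwind of the receptor contribute, the crosswind integral
#' within a slice is exact, and the number of slices is doubled until the
#' relative change is below `params$area_tol`. Returns concentration per
#' unit TOTAL area emission rate (s/m^3), the total being spread uniformly
#' over the whole polygon.
#'
#' @param area an [area_source()].
#' @param rec receptor data frame (one or more rows with `x`, `y`, `z`).
#' @inheritParams point_kernel
#' @return numeric vector, one coupling per receptor row.
#' @export
area_source_coupling <- function(area, rec, met, params = dispersion_params()) {
  .area_coupling_multi(area, rec$x, rec$y, rec$z, met, params)
}
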