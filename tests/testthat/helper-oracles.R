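# Independent oracles used by the tests. These deliberately avoid the
# package's adaptive integration and NNLS paths: brute-force sums of the
# point kernel, dense 2-D quadrature, and zoomed grid search.

# near-neutral met record: westerly wind, no mixing lid
neutral_met <- function(wdir = 270, u_ref = 4, L = 1e6, zi = 1e8) {
  list(u_ref = u_ref, z_ref = 10, wdir = wdir, ustar = 0.3, L = L, zi = zi)
}

# fixed N-point Riemann sum of the point kernel along a line source
riemann_line <- function(line, rec, met, params = dispersion_params(),
                         npts = 10001) {
  s <- seq(0, 1, length.out = npts)
  src <- data.frame(x = line$x1 + s * (line$x2 - line$x1),
                    y = line$y1 + s * (line$y2 - line$y1),
                    h = line$h)
  mean(point_kernel(src, rec, met, params, sigma_z0 = line$sigma_z0))
}

# dense cell-midpoint 2-D quadrature of the point kernel over a rectangle
# area source (per unit total emission rate)
quad_area_rect <- function(x0, x1, y0, y1, rec, met,
                           params = dispersion_params(), nx = 2000, ny = 2000,
                           h = 0, sigma_z0 = 0) {
  gx <- x0 + (seq_len(nx) - 0.5) * (x1 - x0) / nx
  gy <- y0 + (seq_len(ny) - 0.5) * (y1 - y0) / ny
  tot <- 0
  for (chunk in split(gx, ceiling(seq_along(gx) / max(1, floor(2e6 / ny))))) {
    g <- expand.grid(x = chunk, y = gy)
    g$h <- h
    tot <- tot + sum(point_kernel(g, rec, met, params, sigma_z0 = sigma_z0))
  }
  tot / (nx * ny)
}

# zoomed grid search for the 2-category non-negative least squares problem
grid_search_nnls2 <- function(A, cvec, spacing_target = 1e-7, m = 41) {
  ls <- qr.solve(A, cvec)
  hw <- rep(max(abs(ls)) + 1, 2)
  ctr <- pmax(ls, 0)
  repeat {
    g1 <- seq(max(ctr[1] - hw[1], 0), ctr[1] + hw[1], length.out = m)
    g2 <- seq(max(ctr[2] - hw[2], 0), ctr[2] + hw[2], length.out = m)
    G <- as.matrix(expand.grid(g1, g2))
    R <- G %*% t(A)
    rss <- rowSums((R - matrix(cvec, nrow(G), length(cvec), byrow = TRUE))^2)
    ctr <- G[which.min(rss), ]
    sp <- max(g1[2] - g1[1], g2[2] - g2[1])
    if (sp < spacing_target) return(as.numeric(ctr))
    hw <- rep(2 * sp, 2)
  }
}

# rotate a scene (points and meteorological wind direction) by `deg` CCW
rotate_xy <- function(x, y, deg) {
  th <- deg * pi / 180
  list(x = x * cos(th) - y * sin(th), y = x * sin(th) + y * cos(th))
}
rotate_wdir <- function(wdir, deg) (wdir - deg) %% 360

# wrappers over internal helpers used in tests
.kriged_field_for_test <- function(gs, vals) plumekrig:::.kriged_field(gs, vals)
.field_at_for_test <- function(f, x, y) plumekrig:::.field_at(f, x, y)
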