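test_that("point kernel reduces to the ground-reflection closed form", {
  met <- neutral_met()
  rec <- data.frame(x = 1000, y = 0, z = 0)
  k <- point_kernel(c(0, 0, 0), rec, met)
  sy <- sigma_y(1000, met); sz <- sigma_z(1000, met)
  expect_equal(k, 1 / (pi * met$u_ref * sy * sz), tolerance = 1e-12)

  # upwind receptor sees nothing
  expect_equal(point_kernel(c(1500, 0, 0), rec, met), 0)
  # crosswind symmetry
  kp <- point_kernel(c(0, 0, 0), data.frame(x = 800, y = 300, z = 2), met)
  km <- point_kernel(c(0, 0, 0), data.frame(x = 800, y = -300, z = 2), met)
  expect_equal(kp, km, tolerance = 1e-12)
  expect_gt(kp, 0)
})

test_that("initial vertical spread enters in quadrature and dilutes ground kernels", {
  met <- neutral_met()
  rec <- data.frame(x = 500, y = 0, z = 0)
  k0 <- point_kernel(c(0, 0, 0), rec, met, sigma_z0 = 0)
  k10 <- point_kernel(c(0, 0, 0), rec, met, sigma_z0 = 10)
  sz <- sigma_z(500, met)
  expect_equal(k10 / k0, sz / sqrt(sz^2 + 100), tolerance = 1e-10)
  expect_lt(k10, k0)
})

test_that("finite line coupling matches a brute-force point sum at any wind angle", {
  met <- neutral_met()
  # crosswind line, receptor 200 m downwind of the midpoint
  ln <- line_source("l", 0, -500, 0, 500, "c", sigma_z0 = 0)
  rec <- data.frame(x = 200, y = 0, z = 2)
  expect_equal(line_source_coupling(ln, rec, met),
               riemann_line(ln, rec, met, npts = 2001),
               tolerance = 5e-3)

  # oblique line
  ln2 <- line_source("l2", -300, -400, 500, 600, "c", sigma_z0 = 5)
  rec2 <- data.frame(x = 900, y = 100, z = 2)
  expect_equal(line_source_coupling(ln2, rec2, met),
               riemann_line(ln2, rec2, met, npts = 5001),
               tolerance = 5e-3)

  # wind parallel to the line: finite and close to the brute-force sum
  ln3 <- line_source("l3", 0, 0, 5000, 100, "c", sigma_z0 = 0)
  rec3 <- data.frame(x = 6000, y = 150, z = 2)
  v <- line_source_coupling(ln3, rec3, met)
  expect_true(is.finite(v) && v > 0)
  expect_equal(v, riemann_line(ln3, rec3, met, npts = 20001), tolerance = 5e-3)

  # a vanishingly short line behaves like a point source
  ln4 <- line_source("l4", 100, -50, 100, -50 + 1e-12, "c", sigma_z0 = 0)
  rec4 <- data.frame(x = 600, y = 0, z = 2)
  expect_equal(line_source_coupling(ln4, rec4, met),
               point_kernel(c(100, -50, 0), rec4, met), tolerance = 1e-6)
})

test_that("scene rotation leaves line and area couplings invariant", {
  met <- neutral_met()
  ln <- line_source("l", 0, -500, 0, 500, "c", sigma_z0 = 0)
  rec <- data.frame(x = 200, y = 0, z = 2)
  v0 <- line_source_coupling(ln, rec, met)
  ar <- area_source("a", c(0, 3000, 3000, 0), c(0, 0, 3000, 3000), "v")
  reca <- data.frame(x = 3400, y = 1500, z = 2)
  a0 <- area_source_coupling(ar, reca, met)
  for (deg in c(37, 120, 261)) {
    metr <- neutral_met(wdir = rotate_wdir(270, deg))
    lp <- rotate_xy(c(ln$x1, ln$x2), c(ln$y1, ln$y2), deg)
    rp <- rotate_xy(rec$x, rec$y, deg)
    lnr <- line_source("lr", lp$x[1], lp$y[1], lp$x[2], lp$y[2], "c", sigma_z0 = 0)
    expect_equal(line_source_coupling(lnr, data.frame(x = rp$x, y = rp$y, z = 2), metr),
                 v0, tolerance = 5e-3, info = paste("deg", deg))
    ap <- rotate_xy(ar$px, ar$py, deg)
    rpa <- rotate_xy(reca$x, reca$y, deg)
    arr <- area_source("ar", ap$x, ap$y, "v")
    expect_equal(area_source_coupling(arr, data.frame(x = rpa$x, y = rpa$y, z = 2), metr),
                 a0, tolerance = 2e-2, info = paste("deg", deg))
  }
})

test_that("area coupling vanishes upwind and is additive over a partition", {
  met <- neutral_met()
  ar <- area_source("a", c(0, 5000, 5000, 0), c(0, 0, 5000, 5000), "v")
  expect_equal(area_source_coupling(ar, data.frame(x = -3000, y = 2500, z = 2), met), 0)

  p <- dispersion_params(area_tol = 1e-4)
  rec <- data.frame(x = 5400, y = 2100, z = 2)
  whole <- area_source_coupling(ar, rec, met, p)
  a1 <- area_source("a1", c(0, 2000, 2000, 0), c(0, 0, 5000, 5000), "v")
  a2 <- area_source("a2", c(2000, 5000, 5000, 2000), c(0, 0, 5000, 5000), "v")
  split_sum <- (2000 * area_source_coupling(a1, rec, met, p) +
                3000 * area_source_coupling(a2, rec, met, p)) / 5000
  expect_equal(whole, split_sum, tolerance = 2e-3)
})

test_that("area decomposition matches dense quadrature for an interior receptor", {
  met <- neutral_met()
  ar <- area_source("a", c(0, 5000, 5000, 0), c(0, 0, 5000, 5000), "v")
  rec <- data.frame(x = 2500, y = 2500, z = 2)
  mine <- area_source_coupling(ar, rec, met, dispersion_params(area_tol = 1e-4))
  oracle <- quad_area_rect(0, 5000, 0, 5000, rec, met, nx = 600, ny = 600)
  expect_equal(mine, oracle, tolerance = 2e-2)
})

test_that("ground-receptor couplings never increase with initial vertical spread", {
  met <- neutral_met()
  recs <- data.frame(x = c(500, 2000, 8000), y = c(0, 300, -1000), z = 0)
  prev <- rep(Inf, 3)
  for (s0 in c(0, 5, 10, 20, 50)) {
    ln <- line_source("l", 0, -3000, 0, 3000, "c", sigma_z0 = s0)
    cur <- line_source_coupling(ln, recs, met)
    expect_true(all(cur <= prev * (1 + 1e-6)), info = paste("sigma_z0", s0))
    prev <- cur
  }
})

test_that("a capping inversion layer enforces the well-mixed limit far downwind", {
  met <- neutral_met(zi = 150)  # shallow boundary layer
  rec <- data.frame(x = 30000, y = 0, z = 2)   # sigma_z >> zi here
  k <- point_kernel(c(0, 0, 0), rec, met)
  sy <- sigma_y(30000, met)
  expect_equal(k, 1 / (sqrt(2 * pi) * sy * met$u_ref * met$zi) *
                 exp(0), tolerance = 1e-10)
})
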