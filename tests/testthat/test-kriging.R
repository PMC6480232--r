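test_that("empirical semivariogram matches pair-by-pair enumeration", {
  # 4 points on a line, values 0,1,0,1, unit spacing
  emp <- empirical_semivariogram(0:3, rep(0, 4), c(0, 1, 0, 1),
                                 breaks = c(0.5, 1.5, 2.5, 3.5))
  expect_equal(emp$gamma, c(0.5, 0, 0.5))
  expect_equal(emp$n_pairs, c(3L, 2L, 1L))
  expect_equal(emp$lag, c(1, 2, 3))

  # constant field
  emp0 <- empirical_semivariogram(runif(10), runif(10), rep(7, 10), n_bins = 5)
  expect_true(all(emp0$gamma[emp0$n_pairs > 0] == 0))

  # permutation invariance
  set.seed(2)
  x <- runif(30); y <- runif(30); z <- rnorm(30)
  p <- sample(30)
  expect_equal(empirical_semivariogram(x, y, z, n_bins = 8),
               empirical_semivariogram(x[p], y[p], z[p], n_bins = 8))
})

test_that("variogram fitting recovers a noise-free model curve exactly", {
  v <- variogram_model("exponential", nugget = 0.3, psill = 1.8, range = 4000)
  h <- seq(200, 12000, length.out = 12)
  emp <- data.frame(lag = h, gamma = vgm_gamma(v, h), n_pairs = 50L)
  fit <- fit_variogram(emp, "exponential")
  expect_equal(fit$nugget, 0.3, tolerance = 1e-4)
  expect_equal(fit$psill, 1.8, tolerance = 1e-4)
  expect_equal(fit$range, 4000, tolerance = 1e-2)

  # pair counts weight the fit: perturbing a heavy bin moves it more
  emp_small <- emp; emp_small$n_pairs[3] <- 1L; emp_small$gamma[3] <- emp$gamma[3] + 1
  emp_big <- emp; emp_big$n_pairs[3] <- 5000L; emp_big$gamma[3] <- emp$gamma[3] + 1
  f_small <- fit_variogram(emp_small, "exponential")
  f_big <- fit_variogram(emp_big, "exponential")
  dev <- function(f) abs(f$nugget - 0.3) + abs(f$psill - 1.8) + abs(f$range - 4000) / 4000
  expect_lt(dev(f_small), dev(f_big))

  expect_warning(f0 <- fit_variogram(data.frame(lag = 1:4, gamma = 0,
                                                n_pairs = 10L)), "zero")
  expect_equal(f0$psill, 0)
  expect_error(fit_variogram(data.frame(lag = 1, gamma = 1, n_pairs = 1L)),
               ">= 3")
})

test_that("variogram models respect their structural invariants", {
  for (fam in c("exponential", "spherical", "gaussian")) {
    v <- variogram_model(fam, nugget = 0.4, psill = 2, range = 3000)
    expect_equal(vgm_gamma(v, 0), 0.4)
    h <- seq(0, 30000, length.out = 500)
    expect_true(all(diff(vgm_gamma(v, h)) >= -1e-12))
    expect_equal(vgm_gamma(v, 1e7), 2.4, tolerance = 1e-3)
    expect_equal(vgm_cov(v, 0), 2.4)
  }
})

test_that("simple kriging weights solve the covariance system and interpolate exactly", {
  v <- variogram_model("exponential", nugget = 0, psill = 2, range = 1500)
  x <- c(0, 1000, 400); y <- c(0, 200, 900); z <- c(5, 8, 6.5)
  sk <- simple_krige(x, y, z, mean = 6, v, tx = 300, ty = 300)
  # direct 3x3 solve
  C <- vgm_cov(v, as.matrix(dist(cbind(x, y))))
  c0 <- vgm_cov(v, sqrt((x - 300)^2 + (y - 300)^2))
  w <- solve(C, c0)
  expect_equal(sk$pred, 6 + sum(w * (z - 6)), tolerance = 1e-10)
  expect_equal(sk$var, 2 - sum(w * c0), tolerance = 1e-10)

  # exact interpolation at data sites with zero nugget
  at_data <- simple_krige(x, y, z, 6, v, x, y)
  expect_equal(at_data$pred, z, tolerance = 1e-8)
  expect_equal(at_data$var, rep(0, 3), tolerance = 1e-8)

  # far target reverts to the mean with full sill variance
  far <- simple_krige(x, y, z, 6, v, 1e6, 1e6)
  expect_equal(far$pred, 6, tolerance = 1e-6)
  expect_equal(far$var, 2, tolerance = 1e-6)
  expect_true(all(sk$var <= 2 + 1e-12))

  expect_error(simple_krige(c(0, 0), c(1, 1), c(1, 2), 0, v, 5, 5), "duplicate")
})

test_that("kriging predictions shift with translations and constant offsets", {
  v <- variogram_model("exponential", nugget = 0.1, psill = 1, range = 800)
  set.seed(4)
  x <- runif(8, 0, 2000); y <- runif(8, 0, 2000); z <- rnorm(8, 10, 1)
  a <- simple_krige(x, y, z, 10, v, 777, 888)
  b <- simple_krige(x + 5000, y - 3000, z, 10, v, 777 + 5000, 888 - 3000)
  expect_equal(a$pred, b$pred, tolerance = 1e-10)
  expect_equal(a$var, b$var, tolerance = 1e-10)
  d <- simple_krige(x, y, z + 3, 13, v, 777, 888)
  expect_equal(d$pred, a$pred + 3, tolerance = 1e-10)
})

test_that("the modeled grid field is consistent with the transfer matrix and linear in emissions", {
  sc <- tiny_scenario()
  met <- sc$met[1:8, ]
  gs <- grid_spec(0, 40000, 0, 80000, res = 8000)
  # receptors placed exactly on grid nodes for a direct comparison
  rec <- receptors(c("g1", "g2"), x = c(16000, 24000), y = c(8000, 40000))
  tm <- suppressMessages(build_transfer_matrix(sc$sources, rec, met))
  E <- sc$E_true
  fld <- suppressMessages(model_grid_field(sc$sources, E, met, gs))
  ix <- match(rec$x, fld$gx); iy <- match(rec$y, fld$gy)
  expect_equal(fld$values[cbind(ix, iy)],
               unname(as.numeric(tm$values %*% E)), tolerance = 5e-3)

  fld2 <- suppressMessages(model_grid_field(sc$sources, 2 * E, met, gs))
  expect_equal(fld2$values, 2 * fld$values, tolerance = 1e-12)
})

test_that("residual kriging reproduces the model field and the observations in the exact limits", {
  sc <- tiny_scenario()
  gs <- grid_spec(0, 40000, 0, 80000, res = 8000)
  set.seed(6)
  fake_field <- .kriged_field_for_test(gs, 5 + runif(length(gs$gx) * length(gs$gy)))
  rec <- sc$receptors
  model_rec <- .field_at_for_test(fake_field, rec$x, rec$y)

  # zero residuals: the map IS the model field
  m0 <- residual_krige_map(fake_field, rec, model_rec,
                           model_at_receptors = model_rec,
                           v = variogram_model("exponential", 0, 1, 5000))
  expect_equal(m0$values, fake_field$values, tolerance = 1e-10)

  # zero nugget: the map honors the observations at the receptors
  obs <- model_rec + rnorm(nrow(rec), 0, 0.5)
  v0 <- variogram_model("exponential", nugget = 0, psill = 0.3, range = 8000)
  m1 <- residual_krige_map(fake_field, rec, obs, model_at_receptors = model_rec,
                           v = v0, floor_zero = FALSE)
  # evaluate the kriged residual surface directly at receptor locations
  r <- obs - model_rec
  back <- simple_krige(rec$x, rec$y, r, 0, v0, rec$x, rec$y)
  expect_equal(back$pred, r, tolerance = 1e-6)
  expect_s3_class(m1, "kriged_field")
  expect_equal(attr(m1, "residuals")$residual, r)
})

test_that("ESRI ASCII export writes a well-formed node-registered grid", {
  gs <- grid_spec(0, 4000, 0, 6000, res = 1000)
  fld <- .kriged_field_for_test(gs, seq_len(5 * 7))
  p <- tempfile(fileext = ".asc")
  write_asc(fld, p, csv = TRUE)
  ll <- readLines(p)
  expect_equal(ll[1], "ncols 5")
  expect_equal(ll[2], "nrows 7")
  expect_length(ll, 6 + 7)
  first_row <- as.numeric(strsplit(ll[7], " ")[[1]])
  expect_equal(first_row, fld$values[, 7])  # top line = northernmost row
  csv <- read.csv(paste0(p, ".csv"))
  expect_equal(nrow(csv), 35L)
})
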