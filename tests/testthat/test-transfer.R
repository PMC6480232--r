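three_hour_met <- function() {
  surface_met(sprintf("2017-01-01T%02d:00:00", 0:2),
              u_ref = c(3, 4, 5), wdir = c(270, 250, 290),
              ustar = c(0.3, 0.25, 0.4), L = c(-100, 1e6, 60),
              zi = c(1000, 800, 300))
}

test_that("short-ton emission rates convert to g/s", {
  expect_equal(tons_per_day_to_g_per_s(0), 0)
  expect_equal(tons_per_day_to_g_per_s(1), 907184.74 / 86400, tolerance = 1e-12)
  expect_equal(tons_per_day_to_g_per_s(1), 10.49982, tolerance = 1e-6)
  expect_equal(tons_per_day_to_g_per_s(12.4), 12.4 * 907184.74 / 86400,
               tolerance = 1e-12)
  expect_equal(tons_per_day_to_g_per_s(12.4), 130.198, tolerance = 1e-4)
  expect_error(tons_per_day_to_g_per_s(-1), "non-negative")
})

test_that("hourly coupling matrix composes the dispersion kernels", {
  met <- as.list(three_hour_met()[1, ])
  ln <- line_source("l", 0, -1000, 0, 1000, "West Desert")
  ar <- area_source("a", c(2000, 6000, 6000, 2000), c(-2000, -2000, 2000, 2000),
                    "Valley")
  rec <- receptors(c("r1", "r2"), x = c(3000, 7000), y = c(0, 500))
  M <- hourly_unit_couplings(list(ln, ar), rec, met)
  expect_equal(dim(M), c(2L, 2L))
  expect_equal(unname(M[, "l"]), unname(line_source_coupling(ln, rec, met)))
  expect_equal(unname(M[, "a"]), unname(area_source_coupling(ar, rec, met)))
  expect_true(all(M >= 0))
})

test_that("transfer matrix is the converted mean of per-hour grouped couplings", {
  met <- three_hour_met()
  ln1 <- line_source("l1", 0, -1000, 0, 1000, "West Desert")
  ln2 <- line_source("l2", 0, 1000, 0, 4000, "West Desert")
  ar <- area_source("a", c(2000, 6000, 6000, 2000), c(-2000, -2000, 2000, 2000),
                    "Valley")
  sources <- list(ln1, ln2, ar)
  rec <- receptors(c("r1", "r2"), x = c(3000, 7000), y = c(0, 500))
  g <- default_grouping(sources)
  # length-proportional allocation within West Desert: 2 km and 3 km lines
  expect_equal(g$weight[g$id == "l1"], 0.4)
  expect_equal(g$weight[g$id == "l2"], 0.6)
  expect_equal(sum(g$weight[g$category == "West Desert"]), 1)

  tm <- suppressMessages(build_transfer_matrix(sources, rec, met))
  expect_s3_class(tm, "transfer_matrix")
  expect_equal(tm$n_hours_used, 3L)
  expect_true(all(tm$values >= 0))

  # hand-computed hour-by-hour average
  acc <- matrix(0, 2, 2)
  for (hh in 1:3) {
    m <- as.list(met[hh, ])
    M <- hourly_unit_couplings(sources, rec, m)
    acc <- acc + cbind(0.4 * M[, "l1"] + 0.6 * M[, "l2"], M[, "a"])
  }
  expected <- acc / 3 * tons_per_day_to_g_per_s(1) * 1e6
  expect_equal(unname(tm$values), unname(expected), tolerance = 1e-12)
})

test_that("calm hours are excluded and sub-period averages recombine exactly", {
  met <- three_hour_met()
  ln <- line_source("l", 0, -1000, 0, 1000, "West Desert")
  rec <- receptors("r1", 500, 0)
  tm3 <- suppressMessages(build_transfer_matrix(list(ln), rec, met))

  met_calm <- rbind(met, surface_met("2017-01-01T03:00:00", 2, 270, 0.05, 100, 200))
  class(met_calm) <- class(met)
  tm4 <- suppressMessages(build_transfer_matrix(list(ln), rec, met_calm))
  expect_equal(tm4$values, tm3$values)
  expect_equal(tm4$n_hours_used, 3L)

  tmA <- suppressMessages(build_transfer_matrix(list(ln), rec, met[1, ]))
  tmB <- suppressMessages(build_transfer_matrix(list(ln), rec, met[2:3, ]))
  expect_equal((1 * tmA$values + 2 * tmB$values) / 3, tm3$values,
               tolerance = 1e-12)

  all_calm <- surface_met("2017-01-01T00:00:00", 2, 270, 0.05, 100, 200)
  expect_error(suppressMessages(suppressWarnings(
    build_transfer_matrix(list(ln), rec, all_calm))), "no usable")
})

test_that("receptor permutation permutes rows and weights act linearly", {
  met <- three_hour_met()
  ln1 <- line_source("l1", 0, -1000, 0, 1000, "c1")
  ln2 <- line_source("l2", 0, 1000, 0, 3000, "c1")
  rec <- receptors(c("r1", "r2", "r3"), x = c(500, 1500, 2500), y = c(0, 100, -100))
  g1 <- data.frame(id = c("l1", "l2"), category = "c1", weight = c(0.5, 0.5))
  g2 <- data.frame(id = c("l1", "l2"), category = "c1", weight = c(1, 0))
  tm1 <- suppressMessages(build_transfer_matrix(list(ln1, ln2), rec, met, grouping = g1))
  tm2 <- suppressMessages(build_transfer_matrix(list(ln1, ln2), rec, met, grouping = g2))
  tm_l2only <- suppressMessages(build_transfer_matrix(
    list(ln1, ln2), rec, met, grouping = data.frame(id = c("l1", "l2"),
                                                    category = "c1",
                                                    weight = c(0, 1))))
  expect_equal(tm1$values, 0.5 * tm2$values + 0.5 * tm_l2only$values,
               tolerance = 1e-12)

  perm <- c(3, 1, 2)
  tmp <- suppressMessages(build_transfer_matrix(list(ln1, ln2), rec[perm, ], met,
                                                grouping = g1))
  expect_equal(unname(tmp$values), unname(tm1$values[perm, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("transfer matrices round-trip through CSV with metadata", {
  tm <- tiny_transfer()
  p <- tempfile(fileext = ".csv")
  write_transfer_matrix(tm, p, config_md5 = "abc")
  tm2 <- read_transfer_matrix(p)
  expect_equal(tm2$values, tm$values, tolerance = 1e-12)
  expect_equal(tm2$categories, tm$categories)
  expect_equal(tm2$n_hours_used, tm$n_hours_used)
  expect_equal(tm2$config_md5, "abc")
})
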