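test_that("spatial normalization leaves a flat plate unchanged and preserves the plate median", {
  g <- uniform_plate(500)
  out <- spatial_normalize(g, window = 9)
  expect_equal(out$area, g$area, tolerance = 1e-12)

  set.seed(21)
  a <- matrix(rlnorm(32 * 48, log(400), 0.4), 32, 48)
  a[sample(length(a), 40)] <- NA
  g <- plate_grid(a, "P", "Q", "uninduced")
  out <- spatial_normalize(g, 9)
  expect_equal(median(out$area, na.rm = TRUE), median(a, na.rm = TRUE),
               tolerance = 1e-9)
  expect_identical(is.na(out$area), is.na(a))      # never fills missing
  expect_true(all(out$area >= 0, na.rm = TRUE))
})

test_that("spatial normalization flattens a 2-fold corner-to-corner gradient", {
  # multiplicative linear gradient, 2-fold corner to corner
  grad <- outer(0:31, 0:47, function(r, c) 2^((r / 31 + c / 47) / 2))
  g <- plate_grid(500 * grad, "P", "Q", "uninduced")
  out <- spatial_normalize(g, window = 9)
  pm <- median(out$area)
  row_med <- apply(out$area[5:28, ], 1, median)
  expect_true(all(abs(row_med / pm - 1) < 0.02))
})

test_that("spatial normalization validates its inputs", {
  g <- uniform_plate(500)
  expect_error(spatial_normalize(g, window = 8), "odd")
  expect_error(spatial_normalize(g, window = 1), "odd")
  empty <- plate_grid(matrix(NA_real_, 32, 48), "P", "Q", "uninduced")
  expect_error(spatial_normalize(empty, 9), "non-missing|degenerate")
  dead <- plate_grid(matrix(0, 32, 48), "P", "Q", "uninduced")
  expect_error(spatial_normalize(dead, 9), "degenerate")
})

test_that("row/column normalization equalizes row medians and preserves the plate median", {
  a <- matrix(400, 32, 48)
  a[7, ] <- 800                          # one row uniformly doubled
  g <- plate_grid(a, "P", "Q", "uninduced")
  out <- rowcol_normalize(g)
  pm <- median(out$area)
  expect_equal(median(out$area[7, ]), pm, tolerance = 1e-9)
  expect_equal(pm, median(a), tolerance = 1e-9)

  # flat plate unchanged
  flat <- rowcol_normalize(uniform_plate(250))
  expect_equal(flat$area, matrix(250, 32, 48), tolerance = 1e-12)

  # pure row effects: every output row median equals the plate median
  set.seed(3)
  rowfac <- exp(rnorm(32, 0, 0.2))
  g2 <- plate_grid(500 * matrix(rowfac, 32, 48), "P", "Q", "uninduced")
  out2 <- rowcol_normalize(g2)
  rm <- apply(out2$area, 1, median)
  expect_true(all(abs(rm / median(out2$area) - 1) < 1e-9))
})

test_that("jackknife filter matches the leave-one-out variance oracle", {
  expect_identical(jackknife_filter(c(100, 100, 100, 100)),
                   rep(FALSE, 4))
  expect_identical(jackknife_filter(c(100, 100, 100, 500)),
                   c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(jackknife_filter(c(1, 2, 3, 4)), rep(FALSE, 4))

  set.seed(7)
  for (i in 1:500) {
    x <- rlnorm(4, log(300), 0.5)
    if (i %% 3 == 0) x[sample(4, 1)] <- x[sample(4, 1)] * 8
    if (i %% 7 == 0) x[sample(4, 1)] <- NA
    expect_identical(jackknife_filter(x), oracle_jackknife(x))
  }
})

test_that("jackknife filter skips small sets and flags at most one replicate", {
  f <- jackknife_filter(c(100, 900, NA, NA))
  expect_identical(as.logical(f), rep(FALSE, 4))
  expect_true(attr(f, "skipped"))
  set.seed(9)
  for (i in 1:200) {
    x <- rlnorm(4, log(300), 1)
    expect_lte(sum(jackknife_filter(x)), 1)
  }
})

test_that("filters are monotone in their thresholds", {
  set.seed(13)
  for (i in 1:100) {
    x <- rlnorm(4, log(300), 0.8)
    f_loose <- jackknife_filter(x, fraction = 0.95)
    f_tight <- jackknife_filter(x, fraction = 0.7)
    # raising the fraction never flags more
    expect_true(all(f_tight | !f_loose))
  }
  mi <- runif(50, 0, 400); mu <- runif(50, 0, 400)
  expect_true(all(low_area_filter(mi, mu, 300) |
                    !low_area_filter(mi, mu, 400)))
})

test_that("low-area filter drops strains below the median-sum threshold", {
  expect_false(low_area_filter(150, 200, 400))   # 350 < 400 -> drop
  expect_true(low_area_filter(400, 0, 400))      # boundary: 400 not < 400
  expect_true(low_area_filter(250, 200, 400))
})

test_that("strains dropped by the low-area filter vanish from every query", {
  sim <- tiny_sim(150, seed = 31, baseline_log_sd = 0.6)
  fit <- suppressMessages(score_screen(sim))
  r <- fit$records
  retained <- split(r$strain_id[r$filter_flags != "low_area"],
                    r$query_id[r$filter_flags != "low_area"])
  expect_gt(length(fit$dropped_strains), 0)
  expect_identical(retained[[1]], retained[[2]])
  expect_true(all(!fit$dropped_strains %in% unlist(retained)))
})
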