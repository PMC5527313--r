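test_that("replicate differentials pair induced and uninduced colonies by slot", {
  obs <- data.frame(
    strain_id = "A", query_id = "Q", layout_id = "T1",
    condition = rep(c("induced", "uninduced"), each = 4),
    slot = rep(1:4, 2),
    area = c(rep(100, 4), rep(200, 4)),
    kept = TRUE, stringsAsFactors = FALSE)
  d <- replicate_differentials(obs, "Q")
  expect_equal(d$d, rep(-1, 4))

  # one induced slot missing -> 3 pairs
  obs$area[2] <- NA
  d <- replicate_differentials(obs, "Q")
  expect_equal(nrow(d), 3)
  expect_equal(sort(d$slot), c(1, 3, 4))

  # zero areas dropped
  obs$area[2] <- 100; obs$area[5] <- 0
  d <- replicate_differentials(obs, "Q")
  expect_equal(nrow(d), 3)
})

test_that("replicate differentials match a per-slot log-ratio recomputation", {
  sim <- tiny_sim(50, seed = 41, missing_prob = 0.03)
  fit <- suppressMessages(score_screen(sim))
  obs <- fit$observations
  d <- replicate_differentials(obs, "Q02")
  kept <- obs[obs$kept & obs$query_id == "Q02", ]
  for (i in sample(nrow(d), 25)) {
    ai <- kept$area[kept$condition == "induced" &
                      kept$strain_id == d$strain_id[i] &
                      kept$slot == d$slot[i] & kept$layout_id == d$layout_id[i]]
    au <- kept$area[kept$condition == "uninduced" &
                      kept$strain_id == d$strain_id[i] &
                      kept$slot == d$slot[i] & kept$layout_id == d$layout_id[i]]
    expect_equal(d$d[i], log2(ai) - log2(au), tolerance = 1e-12)
  }
})

test_that("variance prior collapses correctly in its limits", {
  # all variances identical -> d0 = Inf, every posterior equals that variance
  pr <- fit_variance_prior(rep(0.04, 100), df = 3)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.04)
  expect_equal(moderate_variances(rep(0.04, 5), 3, pr), rep(0.04, 5))
  # d0 = 0 -> no moderation
  pr0 <- structure(list(d0 = 0, s0_sq = 1), class = "variance_prior")
  s2 <- c(0.01, 0.5, 2)
  expect_equal(moderate_variances(s2, 3, pr0), s2)
})

test_that("variance prior recovers known parameters from simulated variances", {
  set.seed(19)
  d0 <- 4; s0 <- 0.04; df <- 3; n <- 5000
  truevar <- d0 * s0 / rchisq(n, d0)              # scaled inverse chi-square
  s2 <- truevar * rchisq(n, df) / df
  pr <- fit_variance_prior(s2, df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.15)
})

test_that("variance prior agrees with the reference empirical-Bayes fit", {
  set.seed(29)
  s2 <- (6 * 0.05 / rchisq(2000, 6)) * rchisq(2000, 3) / 3
  pr <- fit_variance_prior(s2, df = 3)
  ref <- limma::fitFDist(s2, df1 = 3)
  expect_equal(pr$s0_sq, ref$scale, tolerance = 1e-6)
  expect_equal(pr$d0, ref$df2, tolerance = 1e-6)
  sq <- limma::squeezeVar(s2, df = 3)
  expect_equal(moderate_variances(s2, 3, pr), sq$var.post, tolerance = 1e-6)
})

test_that("threshold test reduces to the two-sided moderated t at threshold 1", {
  pr <- structure(list(d0 = 4, s0_sq = 0.04), class = "variance_prior")
  set.seed(11)
  delta <- rnorm(50, 0, 0.5)
  s2p <- moderate_variances(0.04 * rchisq(50, 3) / 3, 3, pr)
  tt <- threshold_test(delta, s2p, n_pairs = 4, prior = pr,
                       fold_threshold = 1, null_center = 0)
  se <- sqrt(s2p / 4)
  p_ref <- 2 * pt(abs(delta) / se, df = 4 - 1 + 4, lower.tail = FALSE)
  expect_equal(tt$p_value, p_ref, tolerance = 1e-10)
})

test_that("threshold test is centered and monotone", {
  pr <- structure(list(d0 = Inf, s0_sq = 0.04), class = "variance_prior")
  # null-centered effect: p >= 0.5, approaching 1 as tau/se grows
  p0 <- threshold_test(0, 0.04, 4, pr, fold_threshold = 1.3)$p_value
  expect_gte(p0, 0.5)
  p_big <- threshold_test(0, 0.0004, 4, pr, fold_threshold = 1.3)$p_value
  expect_gt(p_big, 0.999)
  # p non-decreasing in tau at fixed delta, se
  taus <- c(1, 1.1, 1.3, 1.6, 2)
  ps <- vapply(taus, function(f)
    threshold_test(0.8, 0.04, 4, pr, fold_threshold = f)$p_value, 0)
  expect_true(all(diff(ps) >= 0))
  # p non-increasing in |delta| at fixed tau, se
  ps2 <- vapply(c(0, 0.3, 0.6, 1, 2), function(d)
    threshold_test(d, 0.04, 4, pr, fold_threshold = 1.3)$p_value, 0)
  expect_true(all(diff(ps2) <= 0))
})

test_that("threshold test handles zero standard errors deterministically", {
  pr <- structure(list(d0 = Inf, s0_sq = 0), class = "variance_prior")
  expect_equal(threshold_test(1, 0, 4, pr, 1.3)$p_value, 0)
  expect_equal(threshold_test(0.1, 0, 4, pr, 1.3)$p_value, 1)
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(37)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))          # monotone in p
  perm <- sample(200)
  expect_equal(bh_adjust(p[perm]), q[perm])          # permutation invariant
})

test_that("classification gates on the control window, q-value and S thresholds", {
  cfg <- test_config()
  expect_equal(classify_interactions(0.45, 0.01, 1.0, TRUE, cfg), "positive")
  expect_equal(classify_interactions(0.45, 0.20, 1.0, TRUE, cfg), "none")
  expect_equal(classify_interactions(-0.50, 0.001, 0.6, TRUE, cfg),
               "filtered")
  expect_equal(classify_interactions(-0.50, 0.001, 0.8, TRUE, cfg),
               "negative")
  # closed window: boundary control responses stay eligible
  expect_equal(classify_interactions(0.45, 0.01, 1.3, TRUE, cfg), "positive")
  expect_equal(classify_interactions(0.2, 0.01, 1.0, TRUE, cfg), "none")
  expect_equal(classify_interactions(0.45, 0.01, 1.0, FALSE, cfg),
               "filtered")
})
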