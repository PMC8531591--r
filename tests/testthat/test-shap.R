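fit_small_model <- function(d, nrounds = 8) {
  hspmark:::fit_booster(d$x, d$y, default_point(nrounds = nrounds))
}

test_that("Shapley efficiency holds to double precision per sample", {
  d <- make_signal_data(n = 120, n_noise = 3, effect = 2, seed = 61)
  model <- fit_small_model(d, nrounds = 15)
  at <- shapley_attributions(model, d$x, orientation = "cancer")
  expect_lt(max(abs(at$base_value + rowSums(at$values) - at$margin)), 1e-6)
  # the exact margins agree with the booster's own float32 predictions
  m32 <- predict(model, xgboost::xgb.DMatrix(d$x, nthread = 1),
                 outputmargin = TRUE)
  expect_lt(max(abs(at$margin - m32)), 1e-4)
})

test_that("attributions match the exhaustive-subset Shapley oracle", {
  d <- make_signal_data(n = 40, n_noise = 3, effect = 2, seed = 62)
  model <- fit_small_model(d, nrounds = 5)
  at <- shapley_attributions(model, d$x, orientation = "cancer")
  brute <- shapley_brute_force(model, d$x)
  expect_lt(max(abs(at$values - brute)), 1e-6)
})

test_that("attributions match the booster's native contribution predictor", {
  d <- make_signal_data(n = 150, n_noise = 4, effect = 1.5, seed = 63)
  model <- fit_small_model(d, nrounds = 20)
  at <- shapley_attributions(model, d$x, orientation = "cancer")
  ctr <- predict(model, xgboost::xgb.DMatrix(d$x, nthread = 1),
                 predcontrib = TRUE)
  expect_lt(max(abs(at$values - ctr[, colnames(d$x)])), 1e-4)
})

test_that("single-stump attributions equal leaf margin minus its mean", {
  withr::with_seed(64, {
    x <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "f"))
    y <- as.integer(x[, 1] > 0)
  })
  model <- hspmark:::fit_booster(
    x, y, c(eta = 1, max_depth = 1, nrounds = 1, subsample = 1,
            colsample_bytree = 1, min_child_weight = 1))
  at <- shapley_attributions(model, x, orientation = "cancer")
  expect_equal(at$values[, 1], at$margin - at$base_value, tolerance = 1e-12)
})

test_that("a model trained on variation-free data attributes nothing", {
  x <- matrix(1, 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c(0L, 1L), 25)
  model <- hspmark:::fit_booster(x, y, default_point(nrounds = 3))
  at <- shapley_attributions(model, x, orientation = "cancer")
  expect_true(all(at$values == 0))
  expect_equal(at$base_value + rowSums(at$values), at$margin,
               tolerance = 1e-12)
  # identical query samples receive identical attributions
  d <- make_signal_data(n = 80, n_noise = 2, effect = 2, seed = 65)
  m2 <- fit_small_model(d)
  same <- d$x[rep(1, 5), , drop = FALSE]
  at2 <- shapley_attributions(m2, same, orientation = "cancer")
  expect_equal(apply(at2$values, 2, stats::sd),
               stats::setNames(rep(0, 4), colnames(d$x)))
  expect_equal(stats::sd(at2$margin), 0)
})

test_that("orientation flips the sign convention", {
  d <- make_signal_data(n = 60, n_noise = 2, effect = 2, seed = 66)
  model <- fit_small_model(d)
  can <- shapley_attributions(model, d$x, orientation = "cancer")
  non <- shapley_attributions(model, d$x)  # default: non-cancer margin
  expect_equal(non$values, -can$values)
  expect_equal(non$base_value, -can$base_value)
  # higher signal value pushes toward cancer: negative attribution under
  # the default convention
  hi <- which.max(d$x[, "sig1"])
  expect_lt(non$values[hi, "sig1"], 0)
  # feature-name mismatch is fatal
  xbad <- d$x
  colnames(xbad)[1] <- "other"
  expect_error(shapley_attributions(model, xbad), "mismatch")
})

test_that("family aggregation sums members and preserves efficiency", {
  d <- make_signal_data(n = 60, n_noise = 4, effect = 2, seed = 67)
  model <- fit_small_model(d)
  at <- shapley_attributions(model, d$x, orientation = "cancer")
  fam <- list(SIG = c("sig1", "sig2"), N12 = c("noise1", "noise2"))
  agg <- aggregate_families(at, fam)
  expect_identical(colnames(agg$values),
                   c("SIG", "N12", "noise3", "noise4"))
  expect_equal(agg$values[, "SIG"],
               at$values[, "sig1"] + at$values[, "sig2"])
  expect_equal(at$base_value + rowSums(agg$values), agg$margin,
               tolerance = 1e-9)
  # member order never matters
  agg2 <- aggregate_families(at, list(SIG = c("sig2", "sig1"),
                                      N12 = c("noise2", "noise1")))
  expect_equal(agg$values, agg2$values)
  # identity and error cases
  expect_identical(aggregate_families(at, list())$values, at$values)
  expect_error(aggregate_families(at, list(A = "sig1", B = "sig1")),
               "overlapping")
})

test_that("shap summary ranks planted signal features first", {
  d <- make_signal_data(n = 150, n_noise = 4, effect = 3, seed = 68)
  model <- fit_small_model(d, nrounds = 15)
  at <- shapley_attributions(model, d$x)
  s <- shap_summary(at)
  expect_setequal(s$feature[1:2], c("sig1", "sig2"))
  expect_true(all(diff(s$mean_abs_shap) <= 0))
})

test_that("z-scores standardize per protein and clip at pooled percentiles", {
  co <- generate_cohort(default_cohort_config(seed = 69))
  hm <- zscore_clipped(co$matrix)
  expect_equal(hm$lo_pct, 1)
  expect_equal(hm$hi_pct, 97)
  # all values inside the clip bounds
  expect_gte(min(hm$z_values), hm$clip_lo)
  expect_lte(max(hm$z_values), hm$clip_hi)
  # bounds are the pooled percentiles of the unclipped z matrix
  z <- apply(co$matrix, 2, scale)
  expect_equal(hm$clip_lo, unname(stats::quantile(z, 0.01)))
  expect_equal(hm$clip_hi, unname(stats::quantile(z, 0.97)))
  # clipping is idempotent
  hm2 <- zscore_clipped(co$matrix)
  clip2 <- pmin(pmax(hm$z_values, hm$clip_lo), hm$clip_hi)
  expect_equal(clip2, hm2$z_values)
  # zero-variance protein maps to all-zero z
  m <- co$matrix
  m[, 1] <- 5
  expect_true(all(zscore_clipped(m)$z_values[, 1] == 0))
})
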