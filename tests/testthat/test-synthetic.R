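test_that("scene generation is deterministic under seed and varies across seeds", {
  spec <- scene_spec(n_straight_lines = 4, n_curves = 2, seed = 31)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(unclass(a), unclass(b))
  spec2 <- scene_spec(n_straight_lines = 4, n_curves = 2, seed = 32)
  c <- generate_scene(spec2)
  expect_false(identical(unclass(a), unclass(c)))
  # primitive counts preserved across seeds
  expect_equal(sum(attr(a, "primitives")$type == "line"), 4)
  expect_equal(sum(attr(c, "primitives")$type == "line"), 4)
})

test_that("drawn primitive rasters match their recorded pixel counts", {
  img <- generate_scene(scene_spec(n_straight_lines = 6, n_curves = 0,
                                   texture_noise_sd = 0, seed = 5))
  prim <- attr(img, "primitives")
  expect_true(all(prim$n_pixels >= 40))  # minimum segment length
  # every line is drawn at full length: count dark pixels in the raster
  v <- to_grayscale(img)
  dark <- sum(v < 100)
  # overlaps can only reduce the union, never by more than a few percent here
  expect_lte(dark, sum(prim$n_pixels))
  expect_gte(dark, 0.9 * sum(prim$n_pixels))
})

test_that("curve-only scenes have near-zero SED and near-unit DER", {
  f <- extract_features(generate_scene(scene_spec(n_straight_lines = 0,
                                                  n_curves = 8, seed = 17)))
  expect_lt(f$sed, 0.005)
  expect_gt(f$der, 0.9)
})

test_that("line-only noise-free scenes have near-zero DER", {
  f <- extract_features(generate_scene(scene_spec(n_straight_lines = 10,
                                                  n_curves = 0,
                                                  texture_noise_sd = 0,
                                                  hue_jitter = 0, seed = 23)))
  # line crossings and end caps leave some non-straight residue
  expect_lt(f$der, 0.45)
  expect_gt(f$sed, 0.02)
})

test_that("infeasible contour counts raise a generation error", {
  expect_error(generate_scene(scene_spec(size = c(48, 48),
                                         n_straight_lines = 50, seed = 1)),
               "infeasible")
  expect_error(generate_scene(scene_spec(size = c(8, 8),
                                         n_straight_lines = 1, seed = 1)),
               "too small")
})

test_that("simulated features respect their ranges and seed contract", {
  f1 <- simulate_features(200, seed = 8)
  f2 <- simulate_features(200, seed = 8)
  expect_identical(f1, f2)
  rngs <- feature_ranges()
  for (nm in names(rngs)) {
    expect_gte(min(f1[[nm]]), rngs[[nm]][1])
    expect_lte(max(f1[[nm]]), rngs[[nm]][2])
  }
  # copula correlation induces the requested dependence sign
  k <- length(rngs)
  corr <- diag(k); corr[9, 10] <- corr[10, 9] <- -0.8  # sed vs der
  fc <- simulate_features(800, corr = corr, seed = 9)
  expect_lt(stats::cor(fc$sed, fc$der), -0.6)
})

test_that("rating simulation reduces to the linear predictor at zero noise", {
  feats <- simulate_features(40, seed = 3)
  spec <- rating_sim_spec(n_participants = 4, rating_noise_sd = 0,
                          preference_noise_sd = 0, rt_noise_sd = 0,
                          likert = FALSE, seed = 11)
  r <- simulate_ratings(feats, spec)
  # every participant's naturalness equals the linear predictor exactly
  Z <- vapply(feats[feature_names()], function(x) (x - mean(x)) / stats::sd(x),
              numeric(40))
  beta <- reference_coefs("naturalness")
  eta <- beta[1] + drop(Z %*% beta[-1][feature_names()])
  for (p in 1:4) {
    expect_equal(r$naturalness[r$participant_id == p], eta, tolerance = 1e-12)
  }
  # identical across participants, so between-participant SD is 0
  expect_equal(stats::sd(r$naturalness[r$image_id == 1]), 0)
})

test_that("rating simulation recovers its generating coefficients", {
  feats <- simulate_features(500, seed = 21)
  spec <- rating_sim_spec(n_participants = 52, rating_noise_sd = 0.9,
                          seed = 22)
  r <- simulate_ratings(feats, spec)
  agg <- aggregate_means(zscore_rt(r))
  fit <- fit_ols(feats[feature_names()], agg$mean_naturalness,
                 standardize = "x")
  beta <- reference_coefs("naturalness")
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- stats::setNames(fit$coefficients$se, fit$coefficients$term)
  expect_lt(abs(est[["(Intercept)"]] - beta[["intercept"]]),
            2 * se[["(Intercept)"]] + 1e-8)
  for (nm in feature_names()) {
    expect_lt(abs(est[[nm]] - beta[[nm]]), 3 * se[[nm]])
  }
})

test_that("all-zero slopes produce a null downstream fit", {
  feats <- simulate_features(300, seed = 31)
  coefs <- c(intercept = 4, stats::setNames(rep(0, 10), feature_names()))
  spec <- rating_sim_spec(n_participants = 8, naturalness_coefs = coefs,
                          rating_noise_sd = 1, seed = 32)
  r <- simulate_ratings(feats, spec)
  agg <- aggregate_means(zscore_rt(r))
  fit <- fit_ols(feats[feature_names()], agg$mean_naturalness,
                 standardize = "x")
  expect_lt(fit$r_squared, 0.08)
})

test_that("likert clipping keeps ratings in 1..7", {
  feats <- simulate_features(60, seed = 41)
  spec <- rating_sim_spec(n_participants = 6, rating_noise_sd = 3,
                          likert = TRUE, seed = 42)
  r <- simulate_ratings(feats, spec)
  expect_true(all(r$naturalness %in% 1:7))
  expect_true(all(r$preference %in% 1:7))
})

test_that("interaction dataset recovers generating coefficients exactly at zero noise", {
  d <- simulate_interaction_dataset(1000, noise_sd = 0, seed = 51)
  X <- data.frame(modeled = d$modeled, rt = d$rt,
                  rt_x_modeled = d$rt * d$modeled,
                  non_modeled = d$non_modeled,
                  rt_x_non_modeled = d$rt * d$non_modeled)
  est <- ols_oracle(X, d$preference)
  expect_equal(unname(est[-1]),
               unname(c(0.453, -0.036, -0.247, 0.482, 0.108)),
               tolerance = 1e-10)
})

test_that("a null interaction stays null on refit", {
  d <- simulate_interaction_dataset(
    3000, coefs = c(modeled = 0.5, rt = 0, rt_x_modeled = 0,
                    non_modeled = 0.4, rt_x_non_modeled = 0),
    noise_sd = 0.7, seed = 61)
  fit <- rt_interaction_model(d$preference, d$modeled, d$rt, "modeled")
  b_int <- fit$coefficients[fit$coefficients$term == "rt_x_modeled", ]
  expect_lt(abs(b_int$estimate), 3 * b_int$se)
})
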