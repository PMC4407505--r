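test_that("median split labels and tie handling balance the classes", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  s <- median_split(c(1, 2, 2, 3))
  expect_equal(s[1], "low")
  expect_equal(s[4], "high")
  expect_equal(as.integer(table(s)), c(2L, 2L))  # ties split 1/1
  # odd n: 307 distinct values -> 153 / 154
  set.seed(1)
  s2 <- median_split(stats::rnorm(307))
  expect_equal(sort(as.integer(table(s2))), c(153L, 154L))
  expect_error(median_split(rep(3, 10)), "degenerate")
})

test_that("1-D equal-variance QD reduces to the linear midpoint rule", {
  set.seed(11)
  x <- c(stats::rnorm(100, -1, 1), stats::rnorm(100, 1, 1))
  labels <- rep(c("low", "high"), each = 100)
  model <- qd_fit(matrix(x, ncol = 1), labels)
  # force exactly equal variances and priors to get the closed-form midpoint
  model$models$high$chol <- model$models$low$chol <- matrix(1)
  model$models$high$logdet <- model$models$low$logdet <- 0
  model$models$high$mu <- 1; model$models$low$mu <- -1
  model$priors[] <- 0.5
  mid <- qd_predict(model, matrix(c(-0.01, 0.01), ncol = 1))
  expect_equal(mid$label, c("low", "high"))
  expect_equal(qd_predict(model, matrix(0))$posterior[1, ],
               c(high = 0.5, low = 0.5))
})

test_that("posteriors match an explicit density-ratio oracle", {
  set.seed(21)
  X <- rbind(matrix(stats::rnorm(60 * 3, 0), ncol = 3),
             matrix(stats::rnorm(60 * 3, 1.5), ncol = 3))
  labels <- rep(c("a", "b"), each = 60)
  model <- qd_fit(X, labels)
  xs <- matrix(stats::rnorm(100 * 3, 0.7), ncol = 3)
  pred <- qd_predict(model, xs)
  for (i in 1:100) {
    la <- dmvnorm_oracle(xs[i, ], model$models$a$mu, model$models$a$cov) +
      log(model$priors[["a"]])
    lb <- dmvnorm_oracle(xs[i, ], model$models$b$mu, model$models$b$cov) +
      log(model$priors[["b"]])
    oracle_post_a <- 1 / (1 + exp(lb - la))
    expect_equal(pred$posterior[i, "a"], oracle_post_a, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("QD agrees with an independent reference implementation", {
  set.seed(31)
  X <- rbind(matrix(stats::rnorm(80 * 4), ncol = 4),
             matrix(stats::rnorm(80 * 4, 1), ncol = 4))
  labels <- rep(c("high", "low"), each = 80)
  model <- qd_fit(X, labels)
  ref <- MASS::qda(X, grouping = labels)
  pred <- qd_predict(model, X)
  pref <- stats::predict(ref, X)
  expect_equal(pred$label, as.character(pref$class))
  expect_equal(unname(pred$posterior[, "high"]),
               unname(pref$posterior[, "high"]), tolerance = 1e-8)
})

test_that("well-separated clouds classify perfectly; permuted labels near chance", {
  set.seed(41)
  X <- rbind(matrix(stats::rnorm(40 * 2, 0, 1), ncol = 2),
             matrix(stats::rnorm(40 * 2, 6, 1), ncol = 2))
  labels <- rep(c("low", "high"), each = 40)
  res <- loo_pairwise_accuracy(X, labels)
  expect_equal(res$accuracy, 1)
  expect_equal(dim(res$pair_outcomes), c(40, 40))

  # permutation calibration at n = 200
  set.seed(42)
  Xp <- matrix(stats::rnorm(200 * 4), ncol = 4)
  lp <- rep(c("high", "low"), each = 100)
  accs <- replicate(20, loo_pairwise_accuracy(Xp, sample(lp))$accuracy)
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.55)
})

test_that("pairwise LOO equals the refit-from-scratch oracle", {
  set.seed(51)
  X <- rbind(matrix(stats::rnorm(20 * 2, 0), ncol = 2),
             matrix(stats::rnorm(20 * 2, 1.2), ncol = 2))
  labels <- rep(c("high", "low"), each = 20)
  fast <- loo_pairwise_accuracy(X, labels)
  expect_equal(fast$accuracy, loo_pairwise_oracle(X, labels),
               tolerance = 1e-12)
})

test_that("accuracy is invariant under affine rescaling of a feature", {
  set.seed(61)
  X <- rbind(matrix(stats::rnorm(30 * 3, 0), ncol = 3),
             matrix(stats::rnorm(30 * 3, 0.8), ncol = 3))
  labels <- rep(c("high", "low"), each = 30)
  a1 <- loo_pairwise_accuracy(X, labels)$accuracy
  X2 <- X; X2[, 2] <- 1000 * X2[, 2] - 37
  a2 <- loo_pairwise_accuracy(X2, labels)$accuracy
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("class separation never hurts expected accuracy", {
  set.seed(71)
  mean_acc <- vapply(c(0, 1, 2.5), function(delta) {
    accs <- replicate(10, {
      X <- rbind(matrix(stats::rnorm(25 * 2, 0), ncol = 2),
                 matrix(stats::rnorm(25 * 2, delta), ncol = 2))
      loo_pairwise_accuracy(X, rep(c("high", "low"), each = 25))$accuracy
    })
    mean(accs)
  }, 0)
  expect_true(all(diff(mean_acc) > -0.02))
  expect_gt(mean_acc[3], 0.9)
})

test_that("backward elimination keeps signal, drops collinear duplicates", {
  set.seed(81)
  n <- 60
  signal <- c(stats::rnorm(n / 2, 0, 1), stats::rnorm(n / 2, 2.5, 1))
  X <- data.frame(signal = signal,
                  n1 = stats::rnorm(n), n2 = stats::rnorm(n),
                  n3 = stats::rnorm(n), n4 = stats::rnorm(n))
  labels <- rep(c("low", "high"), each = n / 2)
  res <- backward_elimination(X, labels)
  expect_true("signal" %in% res$features)
  expect_gt(res$accuracy, 0.85)

  # perfectly collinear pair: full fit is singular, elimination resolves it
  X2 <- data.frame(a = signal, b = 2 * signal, c = stats::rnorm(n))
  res2 <- backward_elimination(X2, labels)
  expect_true(is.na(res2$trace$accuracy[1]))
  expect_false(all(c("a", "b") %in% res2$features))
  expect_true(any(c("a", "b") %in% res2$features))
})

test_that("all-noise features stay near chance whatever the subset", {
  set.seed(91)
  X <- as.data.frame(matrix(stats::rnorm(120 * 4), 120, 4))
  labels <- rep(c("high", "low"), each = 60)
  res <- backward_elimination(X, labels)
  expect_gt(res$accuracy, 0.4)
  expect_lt(res$accuracy, 0.62)
})
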