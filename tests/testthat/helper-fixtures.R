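# Shared fixtures and independent oracles for the test suite.

# Solid-color scene image.
solid_image <- function(r, g, b, h = 16, w = 16) {
  px <- array(0L, dim = c(h, w, 3))
  px[, , 1] <- as.integer(r); px[, , 2] <- as.integer(g)
  px[, , 3] <- as.integer(b)
  scene_image(px)
}

# Scene with a flat gray field and hand-drawn dark pixels.
drawn_image <- function(coords, h = 96, w = 128, bg = 160L, fg = 30L) {
  px <- array(bg, dim = c(h, w, 3))
  for (k in seq_len(nrow(coords))) px[coords[k, 1], coords[k, 2], ] <- fg
  scene_image(px)
}

# Hand-built edge map (bypasses Canny) for testing the straightness
# classifier in isolation: weights 1 at the given coords, gradients supplied
# per pixel (constant by default).
manual_edge_map <- function(coords, h = 64, w = 64, gx = 0, gy = 1,
                            weights = 1) {
  wts <- matrix(0, h, w); gxm <- matrix(0, h, w); gym <- matrix(0, h, w)
  idx <- coords[, 1] + (coords[, 2] - 1) * h
  wts[idx] <- weights
  gxm[idx] <- gx; gym[idx] <- gy
  structure(list(weights = wts, gx = gxm, gy = gym, thresholds = NULL),
            class = "edge_map")
}

# Independent OLS oracle: normal equations via solve().
ols_oracle <- function(X, y, intercept = TRUE) {
  Xm <- as.matrix(X)
  if (intercept) Xm <- cbind(`(Intercept)` = 1, Xm)
  drop(solve(t(Xm) %*% Xm, t(Xm) %*% y))
}

# Independent Gaussian log-density oracle (explicit inverse and determinant).
dmvnorm_oracle <- function(x, mu, sigma) {
  d <- length(mu)
  v <- x - mu
  -0.5 * (d * log(2 * pi) + log(det(sigma)) +
            drop(t(v) %*% solve(sigma) %*% v))
}

# Naive pairwise-LOO oracle: refits QDA from scratch for every (high, low)
# pair using qd_fit/qd_predict.
loo_pairwise_oracle <- function(X, labels) {
  X <- as.matrix(X)
  hi <- which(labels == "high"); lo <- which(labels == "low")
  outcomes <- matrix(NA_real_, length(hi), length(lo))
  for (a in seq_along(hi)) {
    for (b in seq_along(lo)) {
      keep <- setdiff(seq_len(nrow(X)), c(hi[a], lo[b]))
      model <- qd_fit(X[keep, , drop = FALSE], labels[keep])
      pred <- qd_predict(model, X[c(hi[a], lo[b]), , drop = FALSE])$label
      outcomes[a, b] <- mean(pred == c("high", "low"))
    }
  }
  mean(outcomes)
}
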