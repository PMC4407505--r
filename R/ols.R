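# Internal: z-score with sample SD, erroring on zero variance.
.zscore <- function(x, what = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero variance in ", what, "; cannot standardize", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Ordinary least squares with full fit bookkeeping
#'
#' Fits `y ~ X` by QR-based least squares (via [stats::lm()]) and returns the
#' coefficient table (estimates, standard errors, t values, exact-t 95%
#' confidence intervals), R-squared, adjusted R-squared, the overall F test,
#' residuals and fitted values.
#'
#' `standardize` controls variable scaling: `"none"` fits raw variables with
#' an intercept; `"x"` z-scores the predictor columns (sample SD) and keeps
#' the response raw, so the intercept equals the mean response; `"xy"`
#' z-scores predictors and response, yielding standardized betas (the
#' intercept is 0 by construction and is omitted from the coefficient table,
#' though it is still estimated).
#'
#' @param X data frame or matrix of predictors (no intercept column).
#' @param y numeric response.
#' @param standardize `"none"`, `"x"`, or `"xy"`.
#' @param conf_level confidence level for the coefficient intervals.
#' @return A `linear_fit`: list with `coefficients` (tibble: `term`,
#'   `estimate`, `se`, `t`, `ci_lower`, `ci_upper`), `r_squared`,
#'   `adj_r_squared`, `f_value`, `df1`, `df2`, `p_value`, `sigma`,
#'   `residuals`, `fitted`, `n`, `k`, `standardized`.
#' @examples
#' X <- data.frame(a = rnorm(50), b = rnorm(50))
#' fit <- fit_ols(X, 2 + 1.5 * X$a + rnorm(50, sd = 0.1))
#' fit$coefficients
#' @export
fit_ols <- function(X, y, standardize = c("none", "x", "xy"),
                    conf_level = 0.95) {
  standardize <- match.arg(standardize)
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in predictors or response")
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= k + 1) stop("need n > k + 1 observations")
  if (is.null(names(X)) || any(names(X) == "")) {
    names(X) <- paste0("x", seq_len(k))
  }
  if (standardize %in% c("x", "xy")) {
    X[] <- lapply(names(X), function(nm) .zscore(X[[nm]], nm))
  }
  yfit <- if (standardize == "xy") .zscore(y, "response") else y

  dat <- cbind(X, .y = yfit)
  fit <- stats::lm(.y ~ ., data = dat)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    bad <- setdiff(names(beta)[is.na(beta)], "(Intercept)")
    stop("rank-deficient predictor matrix; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  df2 <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df2)
  coefs <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, 1]), se = unname(ct[, 2]), t = unname(ct[, 3]),
    ci_lower = unname(ct[, 1] - tcrit * ct[, 2]),
    ci_upper = unname(ct[, 1] + tcrit * ct[, 2])
  )
  if (standardize == "xy") {
    coefs <- coefs[coefs$term != "(Intercept)", ]
  }
  fstat <- sm$fstatistic
  structure(list(
    coefficients = coefs,
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_value = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    sigma = sm$sigma,
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    n = n, k = k, standardized = standardize,
    conf_level = conf_level
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d, k = %d, standardize = \"%s\")\n",
              x$n, x$k, x$standardized))
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("R^2 = %.4f, adj. R^2 = %.4f, F(%d, %d) = %.3f, p = %.3g\n",
              x$r_squared, x$adj_r_squared, x$df1, x$df2, x$f_value,
              x$p_value))
  invisible(x)
}

#' Recover R-squared from a printed F statistic
#'
#' Inverts the overall-F identity of an OLS fit with `k` predictors:
#' `R^2 = k F / (k F + df2)` and
#' `adjusted R^2 = 1 - (1 - R^2)(n - 1)/df2`, with `df2 = n - k - 1`.
#' Useful for consistency-checking reported F / R-squared pairs.
#'
#' @param f observed F statistic (`>= 0`).
#' @param k number of predictors.
#' @param df2 residual degrees of freedom, `n - k - 1`.
#' @param n sample size; defaults to `k + df2 + 1`.
#' @return List with `r_squared` and `adj_r_squared`.
#' @examples
#' r2_from_f(36.73, 10, 296)  # adj. R^2 ~ 0.54
#' @export
r2_from_f <- function(f, k, df2, n = k + df2 + 1) {
  stopifnot(f >= 0, k >= 1, df2 > 0, n == k + df2 + 1)
  r2 <- k * f / (k * f + df2)
  list(r_squared = r2, adj_r_squared = 1 - (1 - r2) * (n - 1) / df2)
}

#' Decompose perceived naturalness into modeled and non-modeled parts
#'
#' Regresses per-image naturalness on the ten image features (predictors
#' z-scored, response on its rating scale) and splits each image's
#' naturalness into the fitted value (*modeled naturalness*, the bottom-up,
#' feature-predictable component) and the residual (*non-modeled
#' naturalness*). Two submodels fitted on the six color features alone and
#' the four spatial features alone give color-modeled and structure-modeled
#' naturalness. By OLS construction `modeled + non_modeled` reproduces the
#' observed naturalness exactly and the residuals have mean zero and are
#' uncorrelated with every feature.
#'
#' @param features data frame with the ten feature columns
#'   (see [feature_names()]); one row per image.
#' @param naturalness numeric vector of per-image mean naturalness ratings.
#' @param image_id optional image identifiers.
#' @return A `naturalness_split`: list with `split` (tibble: `image_id`,
#'   `naturalness`, `modeled`, `non_modeled`, `modeled_color`,
#'   `modeled_structure`) and `fits` (the full, color-only and
#'   structure-only `linear_fit` objects).
#' @export
decompose_naturalness <- function(features, naturalness, image_id = NULL) {
  features <- as.data.frame(features)
  miss <- setdiff(feature_names(), names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (anyNA(features[feature_names()])) {
    stop("feature table contains missing values (images with no edges?)")
  }
  if (length(naturalness) != nrow(features)) {
    stop("one naturalness value per image required")
  }
  if (is.null(image_id)) image_id <- seq_len(nrow(features))
  fit_full <- fit_ols(features[feature_names()], naturalness, standardize = "x")
  fit_color <- fit_ols(features[feature_names("color")], naturalness,
                       standardize = "x")
  fit_structure <- fit_ols(features[feature_names("structure")], naturalness,
                           standardize = "x")
  split <- tibble::tibble(
    image_id = image_id,
    naturalness = naturalness,
    modeled = fit_full$fitted,
    non_modeled = fit_full$residuals,
    modeled_color = fit_color$fitted,
    modeled_structure = fit_structure$fitted
  )
  structure(list(split = split,
                 fits = list(full = fit_full, color = fit_color,
                             structure = fit_structure)),
            class = "naturalness_split")
}
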