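#' Reference regression coefficients used as generator defaults
#'
#' The default generating models of the rating simulators. The
#' `"naturalness"` set gives a 1-7 scale naturalness rating as a linear
#' function of the ten z-scored image features (intercept = mean rating); the
#' `"preference"` set gives standardized betas of preference on the ten
#' z-scored features; `"rt_modeled"` / `"rt_nonmodeled"` give the
#' standardized reaction-time moderation models for the modeled and
#' non-modeled naturalness components; `"color_structure"` gives the
#' standardized model of preference on color-modeled, structure-modeled and
#' non-modeled naturalness plus the color-by-structure product.
#'
#' @param model which coefficient set to return.
#' @return Named numeric vector of coefficients.
#' @export
reference_coefs <- function(model = c("naturalness", "preference",
                                      "rt_modeled", "rt_nonmodeled",
                                      "color_structure")) {
  model <- match.arg(model)
  switch(model,
    naturalness = c(
      intercept = 3.573,
      hue = -0.249, sd_hue = -0.220, sat = -0.756, sd_sat = 0.244,
      bright = 0.069, sd_bright = 0.059, entropy = -0.021,
      ed = 0.717, sed = -0.299, der = 0.582
    ),
    preference = c(
      hue = -0.177, sd_hue = -0.009, sat = -0.089, sd_sat = 0.214,
      bright = 0.085, sd_bright = -0.031, entropy = 0.066,
      ed = 0.008, sed = -0.382, der = 0.123
    ),
    rt_modeled = c(modeled = 0.453, rt = -0.036, rt_x_modeled = -0.247),
    rt_nonmodeled = c(non_modeled = 0.482, rt = 0.069,
                      rt_x_non_modeled = 0.108),
    color_structure = c(modeled_color = 0.362, modeled_structure = 0.533,
                        non_modeled = 0.480, color_x_structure = 0.207)
  )
}

#' Default per-feature sampling ranges for simulated feature tables
#'
#' Independent uniform ranges judged plausible for outdoor scene photographs:
#' channel statistics inside the unit interval, entropy in the upper half of
#' its 0-8 bit range (photographs rarely fall below ~5 bits), edge densities
#' small, and the disorganized edge ratio spanning organized to fully
#' disorganized scenes.
#'
#' @return Named list of `c(min, max)` ranges, one per feature.
#' @export
feature_ranges <- function() {
  list(
    hue = c(0.02, 0.55), sd_hue = c(0.02, 0.30),
    sat = c(0.05, 0.85), sd_sat = c(0.03, 0.40),
    bright = c(0.25, 0.90), sd_bright = c(0.05, 0.35),
    entropy = c(5.0, 7.9), ed = c(0.02, 0.40),
    sed = c(0.00, 0.20), der = c(0.20, 1.00)
  )
}

#' Simulate a table of image features
#'
#' Draws per-image feature vectors from independent uniforms over
#' [feature_ranges()] (or user-supplied ranges). An optional correlation
#' matrix induces dependence through a Gaussian copula.
#'
#' @param n number of images.
#' @param ranges named list of `c(min, max)` per feature.
#' @param corr optional positive-definite correlation matrix
#'   (`length(ranges)` square, in range order).
#' @param seed optional integer seed.
#' @return Tibble with one row per image and one column per feature.
#' @export
simulate_features <- function(n, ranges = feature_ranges(), corr = NULL,
                              seed = NULL) {
  draw <- function() {
    k <- length(ranges)
    if (is.null(corr)) {
      u <- matrix(stats::runif(n * k), n, k)
    } else {
      stopifnot(nrow(corr) == k, ncol(corr) == k)
      z <- matrix(stats::rnorm(n * k), n, k) %*% chol(corr)
      u <- stats::pnorm(z)
    }
    out <- lapply(seq_len(k), function(j) {
      r <- ranges[[j]]
      r[1] + (r[2] - r[1]) * u[, j]
    })
    names(out) <- names(ranges)
    tibble::as_tibble(out)
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}

#' Rating simulation specification
#'
#' Parameters of the participant-rating generator. Naturalness ratings follow
#' the reference naturalness equation on z-scored features plus Gaussian
#' participant noise; preference follows the standardized preference betas
#' around `preference_intercept`; reaction times decrease with the image's
#' modeled naturalness (`rt_slope` < 0 gives the faster-for-natural
#' coupling). RT distribution parameters are package choices (no reference
#' values exist for them) and are stated in the methods vignette.
#'
#' @param n_participants number of raters (default 52); must be even when
#'   `counterbalance` is on.
#' @param naturalness_coefs length-11 vector: intercept then ten feature
#'   slopes (default [reference_coefs()]`("naturalness")`).
#' @param preference_coefs length-10 vector of feature slopes.
#' @param preference_intercept mean preference rating.
#' @param rating_noise_sd SD of per-rating Gaussian noise (naturalness).
#' @param preference_noise_sd SD of per-rating noise (preference).
#' @param rt_baseline,rt_slope,rt_noise_sd reaction-time model: seconds at
#'   average modeled naturalness, change per SD of modeled naturalness, and
#'   residual SD.
#' @param likert round and clip ratings to the 1-7 scale (off by default:
#'   analyses use participant means, which are near-continuous, and
#'   continuous ratings keep parameter recovery unbiased).
#' @param counterbalance assign half the participants to each task order.
#' @param seed optional integer seed.
#' @return A list of class `rating_sim_spec`.
#' @export
rating_sim_spec <- function(n_participants = 52L,
                            naturalness_coefs = reference_coefs("naturalness"),
                            preference_coefs = reference_coefs("preference"),
                            preference_intercept = 4,
                            rating_noise_sd = 0.9,
                            preference_noise_sd = 0.8,
                            rt_baseline = 1.8, rt_slope = -0.12,
                            rt_noise_sd = 0.35,
                            likert = FALSE, counterbalance = TRUE,
                            seed = NULL) {
  if (length(naturalness_coefs) != 11) {
    stop("naturalness_coefs must have length 11 (intercept + 10 slopes)")
  }
  if (length(preference_coefs) != 10) {
    stop("preference_coefs must have length 10")
  }
  stopifnot(rating_noise_sd >= 0, preference_noise_sd >= 0, rt_noise_sd >= 0,
            n_participants >= 2)
  if (counterbalance && n_participants %% 2 != 0) {
    stop("n_participants must be even when counterbalancing")
  }
  structure(list(n_participants = as.integer(n_participants),
                 naturalness_coefs = naturalness_coefs,
                 preference_coefs = preference_coefs,
                 preference_intercept = preference_intercept,
                 rating_noise_sd = rating_noise_sd,
                 preference_noise_sd = preference_noise_sd,
                 rt_baseline = rt_baseline, rt_slope = rt_slope,
                 rt_noise_sd = rt_noise_sd, likert = likert,
                 counterbalance = counterbalance, seed = seed),
            class = "rating_sim_spec")
}

#' Simulate participant ratings and reaction times for a feature table
#'
#' For each participant and image: naturalness = intercept + feature slopes
#' on the z-scored features + Gaussian noise; preference likewise from the
#' preference coefficients; RT = baseline + slope x (z-scored linear
#' predictor of naturalness) + noise, truncated at 0.2 s. With `likert` on,
#' ratings are rounded and clipped to 1-7.
#'
#' @param features data frame with the ten feature columns (no missing
#'   values) and optionally an `image_id` column.
#' @param spec a [rating_sim_spec()].
#' @return Tibble with `participant_id`, `image_id`, `preference`,
#'   `naturalness`, `rt`, `group`.
#' @export
simulate_ratings <- function(features, spec = rating_sim_spec()) {
  stopifnot(inherits(spec, "rating_sim_spec"))
  features <- as.data.frame(features)
  image_id <- if ("image_id" %in% names(features)) features$image_id else
    seq_len(nrow(features))
  miss <- setdiff(feature_names(), names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  Xf <- features[feature_names()]
  if (anyNA(Xf)) stop("feature table has missing values; drop or impute first")
  Z <- vapply(Xf, .zscore, numeric(nrow(Xf)))

  align <- function(b) {
    if (!is.null(names(b)) && all(feature_names() %in% names(b))) {
      b[feature_names()]
    } else {
      b  # unnamed: assume feature_names() order
    }
  }
  eta_nat <- spec$naturalness_coefs[1] +
    drop(Z %*% align(spec$naturalness_coefs[-1]))
  eta_pref <- spec$preference_intercept +
    drop(Z %*% align(spec$preference_coefs))
  # a flat linear predictor (all-zero slopes) carries no RT signal
  z_modeled <- if (stats::sd(eta_nat) == 0) rep(0, length(eta_nat)) else
    .zscore(eta_nat, "modeled naturalness")

  n_img <- nrow(Xf); P <- spec$n_participants
  draw <- function() {
    out <- lapply(seq_len(P), function(p) {
      nat <- eta_nat + stats::rnorm(n_img, 0, spec$rating_noise_sd)
      pref <- eta_pref + stats::rnorm(n_img, 0, spec$preference_noise_sd)
      if (spec$likert) {
        nat <- pmin(pmax(round(nat), 1), 7)
        pref <- pmin(pmax(round(pref), 1), 7)
      }
      rt <- pmax(0.2, spec$rt_baseline + spec$rt_slope * z_modeled +
                   stats::rnorm(n_img, 0, spec$rt_noise_sd))
      tibble::tibble(
        participant_id = p, image_id = image_id,
        preference = pref, naturalness = nat, rt = rt,
        group = if (spec$counterbalance && p > P / 2) "naturalness_first" else
          "preference_first"
      )
    })
    dplyr::bind_rows(out)
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, draw()) else draw()
}

#' Simulate a standardized preference/RT interaction dataset
#'
#' Draws z-scaled modeled naturalness, non-modeled naturalness and RT as
#' independent standard normals and generates preference as
#' `b1 modeled + b2 rt + b3 rt x modeled + b4 non_modeled +
#' b5 rt x non_modeled + noise`. The default noise SD (0.70) makes the
#' simulated preference have approximately unit variance, so the generating
#' coefficients keep their scale when the analysis re-standardizes.
#'
#' @param n number of images.
#' @param coefs named vector with elements `modeled`, `rt`, `rt_x_modeled`,
#'   `non_modeled`, `rt_x_non_modeled` (defaults combine the two reference
#'   moderation models; the RT main effect uses the modeled-component model's
#'   value).
#' @param noise_sd residual SD.
#' @param seed optional integer seed.
#' @return Tibble with `preference`, `modeled`, `non_modeled`, `rt`.
#' @export
simulate_interaction_dataset <- function(n,
                                         coefs = c(
                                           modeled = 0.453, rt = -0.036,
                                           rt_x_modeled = -0.247,
                                           non_modeled = 0.482,
                                           rt_x_non_modeled = 0.108),
                                         noise_sd = 0.70, seed = NULL) {
  need <- c("modeled", "rt", "rt_x_modeled", "non_modeled", "rt_x_non_modeled")
  if (!all(need %in% names(coefs))) {
    stop("coefs must name: ", paste(need, collapse = ", "))
  }
  stopifnot(n >= 10, noise_sd >= 0)
  draw <- function() {
    modeled <- stats::rnorm(n)
    non_modeled <- stats::rnorm(n)
    rt <- stats::rnorm(n)
    preference <- coefs[["modeled"]] * modeled + coefs[["rt"]] * rt +
      coefs[["rt_x_modeled"]] * rt * modeled +
      coefs[["non_modeled"]] * non_modeled +
      coefs[["rt_x_non_modeled"]] * rt * non_modeled +
      stats::rnorm(n, 0, noise_sd)
    tibble::tibble(preference = preference, modeled = modeled,
                   non_modeled = non_modeled, rt = rt)
  }
  if (!is.null(seed)) withr::with_seed(seed, draw()) else draw()
}
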