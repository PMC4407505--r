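#' Regress esthetic preference on the ten image features
#'
#' Fully standardized multiple regression (predictors and response z-scored),
#' so coefficients are standardized betas.
#'
#' @param features data frame with the ten feature columns.
#' @param preference per-image mean preference ratings.
#' @return A `linear_fit`, see [fit_ols()].
#' @export
preference_on_features <- function(features, preference) {
  features <- as.data.frame(features)
  miss <- setdiff(feature_names(), names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  fit_ols(features[feature_names()], preference, standardize = "xy")
}

#' Simple regression of preference on perceived naturalness
#'
#' @param naturalness,preference per-image means.
#' @return A `linear_fit` with the slope's confidence interval.
#' @export
preference_on_naturalness <- function(naturalness, preference) {
  fit_ols(data.frame(naturalness = naturalness), preference,
          standardize = "none")
}

#' Reaction-time moderation model for a naturalness component
#'
#' Tests whether the link between a naturalness component (modeled or
#' non-modeled) and preference depends on how quickly the preference judgment
#' was made. Preference, the component and RT are z-scored across images, the
#' product term is formed from the two z-scored mains (and not re-scaled),
#' and preference is regressed on component, RT and their product. The fit
#' includes an intercept (the product's nonzero mean makes it not exactly
#' zero), which is omitted from the reported table.
#'
#' @param preference,component,rt per-image values; `component` is a column of
#'   the split from [decompose_naturalness()].
#' @param label name used for the component term, e.g. `"modeled"`.
#' @return An `interaction_fit` (a `linear_fit` with a `component` label);
#'   terms are `label`, `"rt"`, `"rt_x_<label>"`.
#' @export
rt_interaction_model <- function(preference, component, rt,
                                 label = "modeled") {
  z_c <- .zscore(component, "component")
  z_rt <- .zscore(rt, "rt")
  X <- stats::setNames(
    data.frame(z_c, z_rt, z_rt * z_c),
    c(label, "rt", paste0("rt_x_", label))
  )
  fit <- fit_ols(X, .zscore(preference, "preference"), standardize = "none")
  fit$coefficients <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  fit$component <- label
  class(fit) <- c("interaction_fit", class(fit))
  fit
}

#' Simple slopes of preference on a naturalness component at fixed RT levels
#'
#' Conditional slope of preference on the component when RT is at its mean
#' and at mean +/- `band` standard deviations:
#' `slope(level) = b_component + b_interaction * level`. Because RT is
#' z-scored in the moderation model, levels are in SD units (negative = fast
#' judgments, positive = slow).
#'
#' @param fit an `interaction_fit` from [rt_interaction_model()].
#' @param band half-width of the RT band in SD units.
#' @return Tibble with `rt_level` (`"fast"`, `"average"`, `"slow"`), `level`
#'   (in SD units) and `slope`.
#' @examples
#' # with coefficients 0.453 (main) and -0.247 (interaction):
#' # fast slope = 0.453 + (-0.247)(-1.5) = 0.8235
#' @export
simple_slopes <- function(fit, band = 1.5) {
  stopifnot(inherits(fit, "interaction_fit"))
  b <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  b_main <- b[[fit$component]]
  b_int <- b[[paste0("rt_x_", fit$component)]]
  levels <- c(-band, 0, band)
  tibble::tibble(
    rt_level = c("fast", "average", "slow"),
    level = levels,
    slope = b_main + b_int * levels
  )
}

#' Regress preference on color- and structure-modeled naturalness
#'
#' All variables (preference, color-modeled naturalness, structure-modeled
#' naturalness, non-modeled naturalness) are z-scored across images; the
#' color-by-structure product is formed from the z-scored mains. Preference is
#' regressed on the two modeled components, the non-modeled component and the
#' product. The intercept is estimated but omitted from the reported table.
#'
#' @param preference per-image mean preference.
#' @param split a `naturalness_split` from [decompose_naturalness()] (or its
#'   `split` tibble).
#' @return A `linear_fit` with terms `modeled_color`, `modeled_structure`,
#'   `non_modeled`, `color_x_structure`.
#' @export
color_structure_model <- function(preference, split) {
  if (inherits(split, "naturalness_split")) split <- split$split
  z_col <- .zscore(split$modeled_color, "modeled_color")
  z_str <- .zscore(split$modeled_structure, "modeled_structure")
  z_non <- .zscore(split$non_modeled, "non_modeled")
  X <- data.frame(modeled_color = z_col, modeled_structure = z_str,
                  non_modeled = z_non, color_x_structure = z_col * z_str)
  fit <- fit_ols(X, .zscore(preference, "preference"), standardize = "none")
  fit$coefficients <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  fit
}
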