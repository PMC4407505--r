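#' Pipeline run configuration
#'
#' Bundles everything one reproducible end-to-end run needs: how many
#' synthetic scenes to draw (a mix of nature-like, urban-like and
#' intermediate specs), the rating simulation parameters, feature-extraction
#' configs, the QD feature subset, and a global seed. Round-trips to JSON via
#' [jsonlite]. Unknown arguments are rejected.
#'
#' @param n_images number of synthetic scenes (default 80).
#' @param image_size `c(H, W)` pixels per scene.
#' @param n_participants simulated raters (even; default 20).
#' @param seed global integer seed; every stage derives its randomness from
#'   it.
#' @param rating_noise_sd,preference_noise_sd per-rating noise SDs.
#' @param qd_subset feature names used for the feature-based QD classifier
#'   (default: the seven-feature subset hue, sat, sd_hue, sd_sat, entropy,
#'   sed, der).
#' @param write_images write each generated scene as a PNG under
#'   `images/` in the run directory.
#' @param save_edge_maps write each scene's weighted edge map as a PNG
#'   (weights 0 / 0.5 / 1 mapped to 0 / 128 / 255) under `edge_maps/`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_images = 80L, image_size = c(96L, 128L),
                            n_participants = 20L, seed = 1L,
                            rating_noise_sd = 0.9, preference_noise_sd = 0.8,
                            qd_subset = c("hue", "sat", "sd_hue", "sd_sat",
                                          "entropy", "sed", "der"),
                            write_images = FALSE, save_edge_maps = FALSE) {
  # the richest QD variant uses 8 predictors and pairwise LOO needs
  # d + 3 members per class after the median split
  stopifnot(n_images >= 24, n_participants %% 2 == 0,
            all(qd_subset %in% feature_names()))
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 rating_noise_sd = rating_noise_sd,
                 preference_noise_sd = preference_noise_sd,
                 qd_subset = qd_subset,
                 write_images = write_images,
                 save_edge_maps = save_edge_maps),
            class = "pipeline_config")
}

# Internal: linear_fit -> plain list for JSON reports.
.fit_report <- function(fit) {
  list(coefficients = as.data.frame(fit$coefficients),
       r_squared = fit$r_squared, adj_r_squared = fit$adj_r_squared,
       f_value = fit$f_value, df1 = fit$df1, df2 = fit$df2,
       p_value = fit$p_value, n = fit$n, standardized = fit$standardized)
}

# Internal: scene specs spanning urban-like to nature-like content.
.scene_spec_mix <- function(n, size, seeds) {
  lapply(seq_len(n), function(i) {
    mix <- (i - 1) / max(1, n - 1)  # 0 = urban-like, 1 = nature-like
    scene_spec(
      size = size,
      n_straight_lines = round((1 - mix) * 12),
      n_curves = round(mix * 9),
      base_hue = 0.06 + 0.3 * mix,
      hue_jitter = 0.01 + 0.05 * mix,
      base_sat = 0.15 + 0.35 * mix,
      sat_gradient_amplitude = 0.3 * mix,
      base_bright = 0.6,
      texture_noise_sd = 0.04 * mix,
      seed = seeds[i]
    )
  })
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates synthetic scenes, extracts the ten features, simulates
#' participant ratings, aggregates them per image, decomposes naturalness
#' into modeled and non-modeled components, fits the preference models
#' (features, naturalness, RT moderation with simple slopes, color/structure
#' decomposition) and runs the QD classification variants. Writes
#' `features.csv`, `ratings.csv`, `image_summary.csv`, `split.csv`,
#' `report.json`, `qd_report.json` and `manifest.json` (config, seed and an
#' MD5 per output) into `out_dir`. Identical config + seed reproduce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly; the manifest is also returned as attribute
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max / 2,
                                       config$n_images + 2))

  # stage 1: scenes + features
  specs <- .scene_spec_mix(config$n_images, config$image_size,
                           seeds[seq_len(config$n_images)])
  if (config$write_images) {
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  }
  if (config$save_edge_maps) {
    dir.create(file.path(out_dir, "edge_maps"), showWarnings = FALSE)
  }
  features <- dplyr::bind_rows(lapply(seq_along(specs), function(i) {
    img <- generate_scene(specs[[i]])
    if (config$write_images) {
      write_scene_image(img, file.path(out_dir, "images",
                                       sprintf("scene_%03d.png", i)))
    }
    if (config$save_edge_maps) {
      em <- weighted_canny(to_grayscale(img))
      png::writePNG(ifelse(em$weights == 1, 1,
                           ifelse(em$weights == 0.5, 128 / 255, 0)),
                    file.path(out_dir, "edge_maps",
                              sprintf("edges_%03d.png", i)))
    }
    dplyr::bind_cols(tibble::tibble(image_id = i), extract_features(img))
  }))
  if (anyNA(features$der)) {
    stop("pipeline stage 'extract': image(s) without edges: ",
         paste(features$image_id[is.na(features$der)], collapse = ", "))
  }
  write_feature_table(features, file.path(out_dir, "features.csv"))

  # stage 2: ratings
  spec <- rating_sim_spec(n_participants = config$n_participants,
                          rating_noise_sd = config$rating_noise_sd,
                          preference_noise_sd = config$preference_noise_sd,
                          seed = seeds[config$n_images + 1])
  ratings <- simulate_ratings(features, spec)
  utils::write.csv(ratings, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE)

  # stage 3: aggregation
  ratings <- zscore_rt(ratings)
  summary_tbl <- aggregate_means(ratings)
  order_pref <- order_effect_test(ratings, "preference")
  order_nat <- order_effect_test(ratings, "naturalness")
  utils::write.csv(summary_tbl, file.path(out_dir, "image_summary.csv"),
                   row.names = FALSE)

  # stage 4: naturalness decomposition
  split <- decompose_naturalness(features, summary_tbl$mean_naturalness,
                                 image_id = summary_tbl$image_id)
  utils::write.csv(split$split, file.path(out_dir, "split.csv"),
                   row.names = FALSE)

  # stage 5: preference models
  fit_pref_feat <- preference_on_features(features,
                                          summary_tbl$mean_preference)
  fit_pref_nat <- preference_on_naturalness(summary_tbl$mean_naturalness,
                                            summary_tbl$mean_preference)
  fit_rt_mod <- rt_interaction_model(summary_tbl$mean_preference,
                                     split$split$modeled,
                                     summary_tbl$mean_z_rt, "modeled")
  fit_rt_non <- rt_interaction_model(summary_tbl$mean_preference,
                                     split$split$non_modeled,
                                     summary_tbl$mean_z_rt, "non_modeled")
  fit_cs <- color_structure_model(summary_tbl$mean_preference, split)
  report <- list(
    order_effect = list(
      preference = list(min_p = order_pref$min_p, t = order_pref$t_at_min),
      naturalness = list(min_p = order_nat$min_p, t = order_nat$t_at_min)
    ),
    preference_on_features = .fit_report(fit_pref_feat),
    preference_on_naturalness = .fit_report(fit_pref_nat),
    naturalness_on_features = .fit_report(split$fits$full),
    rt_by_modeled = .fit_report(fit_rt_mod),
    rt_by_non_modeled = .fit_report(fit_rt_non),
    simple_slopes = list(
      modeled = as.data.frame(simple_slopes(fit_rt_mod)),
      non_modeled = as.data.frame(simple_slopes(fit_rt_non))
    ),
    color_structure = .fit_report(fit_cs)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # stage 6: QD classification variants
  labels <- median_split(summary_tbl$mean_preference)
  qd_variants <- list(
    features = as.data.frame(features[config$qd_subset]),
    modeled = data.frame(modeled = split$split$modeled),
    nonmodeled = data.frame(non_modeled = split$split$non_modeled),
    `modeled+nonmodeled` = data.frame(modeled = split$split$modeled,
                                      non_modeled = split$split$non_modeled),
    `features+nonmodeled` = cbind(as.data.frame(features[config$qd_subset]),
                                  non_modeled = split$split$non_modeled)
  )
  qd_report <- lapply(qd_variants, function(Xv) {
    res <- loo_pairwise_accuracy(Xv, labels)
    list(features = res$features, accuracy = res$accuracy,
         n_high = res$n_high, n_low = res$n_low)
  })
  jsonlite::write_json(qd_report, file.path(out_dir, "qd_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # manifest
  outputs <- c("features.csv", "ratings.csv", "image_summary.csv",
               "split.csv", "report.json", "qd_report.json")
  manifest <- list(
    config = unclass(config), seed = config$seed,
    md5 = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$md5) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- invisible(out_dir)
  attr(out, "manifest") <- manifest
  out
}

#' Write / read a feature table
#'
#' CSV with header `image_id,hue,sd_hue,sat,sd_sat,bright,sd_bright,entropy,
#' ed,sed,der`; a missing disorganized edge ratio (image without edges) is an
#' empty field.
#'
#' @param features tibble with `image_id` and the ten feature columns.
#' @param path CSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_table <- function(features, path) {
  cols <- c("image_id", feature_names())
  stopifnot(all(cols %in% names(features)))
  utils::write.csv(as.data.frame(features)[cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
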