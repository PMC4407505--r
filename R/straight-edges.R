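#' Straight-edge detection configuration
#'
#' @param min_pixels smallest connected component (in pixels) tested for
#'   straightness; smaller fragments are degenerately collinear and are never
#'   classified straight.
#' @param variance_ratio straightness threshold on the ratio of the first to
#'   the second eigenvalue of the component's coordinate covariance,
#'   equivalently `(s1/s2)^2` for the singular values of the centered
#'   coordinate matrix. The default `1e4` corresponds to a singular-value
#'   ratio of 100.
#' @return A list of class `straight_config`.
#' @export
straight_config <- function(min_pixels = 10L, variance_ratio = 1e4) {
  stopifnot(min_pixels >= 3, variance_ratio > 1)
  structure(list(min_pixels = as.integer(min_pixels),
                 variance_ratio = variance_ratio),
            class = "straight_config")
}

#' Detect straight edges by gradient-direction connected components
#'
#' Each edge pixel (weight > 0) is assigned to one of eight orientation bins
#' by its gradient direction `atan2(Gy, Gx)` folded to `[0, 180)` degrees in
#' 22.5-degree bins. Within each bin, 8-connected components are labeled, and
#' every component of at least `cfg$min_pixels` pixels is tested for
#' straightness: with `s1 >= s2` the singular values of the mean-centered
#' `N x 2` coordinate matrix, the component is straight iff `s2 == 0` or
#' `(s1/s2)^2 > cfg$variance_ratio`. The mask is the union of the straight
#' components' pixels. An empty edge map yields an empty set.
#'
#' @param edges an `edge_map` from [weighted_canny()].
#' @param cfg a [straight_config()].
#' @return A `straight_edge_set`: list with `mask` (logical `H x W`) and
#'   `components`, a tibble with one row per tested component
#'   (`component`, `bin`, `n_pixels`, `s1`, `s2`, `straight`, and a
#'   list-column `pixels` of linear pixel indices).
#' @export
straight_edges <- function(edges, cfg = straight_config()) {
  stopifnot(inherits(edges, "edge_map"), inherits(cfg, "straight_config"))
  w <- edges$weights
  mask_edges <- w > 0
  out_mask <- matrix(FALSE, nrow(w), ncol(w))
  rows <- list()
  if (any(mask_edges)) {
    # Bins are phase-shifted by half a bin width so the canonical axis and
    # diagonal orientations fall at bin centers, not on bin boundaries
    # (otherwise numerical jitter splits a straight ridge across two bins).
    theta <- (atan2(edges$gy, edges$gx) * 180 / pi) %% 180
    bin <- pmin(floor(((theta + 11.25) %% 180) / 22.5) + 1L, 8L)
    cid <- 0L
    for (b in 1:8) {
      bmask <- mask_edges & bin == b
      if (!any(bmask)) next
      labels <- label_components(bmask, 8L)
      idx_by_comp <- split(which(labels > 0), labels[labels > 0])
      for (idx in idx_by_comp) {
        if (length(idx) < cfg$min_pixels) next
        cid <- cid + 1L
        coords <- cbind((idx - 1L) %% nrow(w) + 1L,       # row (y)
                        (idx - 1L) %/% nrow(w) + 1L)      # col (x)
        sv <- svd(scale(coords, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
        straight <- sv[2] == 0 || (sv[1] / sv[2])^2 > cfg$variance_ratio
        if (straight) out_mask[idx] <- TRUE
        rows[[cid]] <- tibble::tibble(
          component = cid, bin = b, n_pixels = length(idx),
          s1 = sv[1], s2 = sv[2], straight = straight, pixels = list(idx)
        )
      }
    }
  }
  components <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(component = integer(), bin = integer(),
                   n_pixels = integer(), s1 = double(), s2 = double(),
                   straight = logical(), pixels = list())
  }
  structure(list(mask = out_mask, components = components),
            class = "straight_edge_set")
}

#' Straight edge density
#'
#' Number of pixels on detected straight edges over the total number of image
#' pixels. Each straight pixel counts as 1 regardless of its faint/salient
#' edge weight.
#'
#' @param straight a `straight_edge_set` from [straight_edges()].
#' @return Straight edge density in `[0, 1]`.
#' @export
straight_edge_density <- function(straight) {
  stopifnot(inherits(straight, "straight_edge_set"))
  sum(straight$mask) / length(straight$mask)
}

#' Disorganized edge ratio
#'
#' Share of the total weighted edge mass that does not lie on straight edges:
#' `1 - sum(weights[straight]) / sum(weights)`. High values indicate curved or
#' fragmented (disorganized) edge structure; both numerator and denominator
#' use the faint/salient weights for internal consistency.
#'
#' @param edges an `edge_map` from [weighted_canny()].
#' @param straight the matching `straight_edge_set`.
#' @return Ratio in `[0, 1]`. Errors (class `scenestats_undefined_ratio`) when
#'   the image has no edges at all.
#' @export
disorganized_edge_ratio <- function(edges, straight) {
  stopifnot(inherits(edges, "edge_map"), inherits(straight, "straight_edge_set"))
  total <- sum(edges$weights)
  if (total == 0) {
    stop(structure(class = c("scenestats_undefined_ratio", "error", "condition"),
                   list(message = "disorganized edge ratio undefined: edge density is 0",
                        call = sys.call(-1))))
  }
  1 - sum(edges$weights[straight$mask]) / total
}

#' Extract the ten low-level features of a scene image
#'
#' Computes the six HSV color statistics (channel means and standard
#' deviations), grayscale histogram entropy, weighted Canny edge density (ED),
#' straight edge density (SED) and the disorganized edge ratio (DER). All
#' spatial counts are normalized by the number of pixels, so features are
#' comparable across image sizes. DER is `NA` when the image has no edges.
#'
#' @param image a [scene_image()].
#' @param edge_cfg an [edge_config()].
#' @param straight_cfg a [straight_config()].
#' @param sd_type standard-deviation convention for the color channels, see
#'   [color_statistics()].
#' @return A one-row tibble with columns `hue`, `sd_hue`, `sat`, `sd_sat`,
#'   `bright`, `sd_bright`, `entropy`, `ed`, `sed`, `der`.
#' @examples
#' img <- scene_image(array(rep(128L, 3 * 32 * 32), dim = c(32, 32, 3)))
#' extract_features(img)  # degenerate scene: entropy 0, ed 0, der NA
#' @export
extract_features <- function(image, edge_cfg = edge_config(),
                             straight_cfg = straight_config(),
                             sd_type = "population") {
  image <- scene_image(unclass(image))
  cs <- color_statistics(image, sd_type = sd_type)
  gray <- to_grayscale(image)
  edges <- weighted_canny(gray, edge_cfg)
  straight <- straight_edges(edges, straight_cfg)
  ed <- edge_density(edges)
  der <- if (ed == 0) NA_real_ else disorganized_edge_ratio(edges, straight)
  tibble::tibble(
    hue = cs$hue, sd_hue = cs$sd_hue, sat = cs$sat, sd_sat = cs$sd_sat,
    bright = cs$bright, sd_bright = cs$sd_bright,
    entropy = image_entropy(gray), ed = ed,
    sed = straight_edge_density(straight), der = der
  )
}

#' Names of the ten image features
#'
#' @param set `"all"`, `"color"` (the six HSV statistics) or `"structure"`
#'   (entropy and the three edge statistics).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(set = c("all", "color", "structure")) {
  set <- match.arg(set)
  color <- c("hue", "sd_hue", "sat", "sd_sat", "bright", "sd_bright")
  structure_ <- c("entropy", "ed", "sed", "der")
  switch(set, all = c(color, structure_), color = color, structure = structure_)
}
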