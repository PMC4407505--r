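#' Parametric scene specification
#'
#' Describes a synthetic scene: an HSV base field (hue with uniform jitter, a
#' vertical saturation gradient, brightness with Gaussian texture noise) on
#' which straight line segments and curved contours are drawn in contrasting
#' brightness. Stands in for natural/urban photographs in tests and demos.
#'
#' Straight segments are drawn horizontally or vertically (the grid
#' orientations typical of built structure); their rasters are exactly
#' collinear, so their edge ridges satisfy the straightness criterion at any
#' length. Curves are circle arcs with radius in `[8, 18]` pixels, keeping
#' their curvature bounded away from zero so no arc can pass the straightness
#' test.
#'
#' @param size image size `c(H, W)` in pixels.
#' @param n_straight_lines number of straight segments (each >= 40 px).
#' @param n_curves number of curved (arc) contours.
#' @param base_hue,hue_jitter hue center and half-width of its uniform jitter.
#' @param base_sat,sat_gradient_amplitude saturation center and amplitude of a
#'   top-to-bottom linear gradient.
#' @param base_bright base brightness of the field.
#' @param texture_noise_sd SD of Gaussian brightness noise per pixel.
#' @param seed integer seed; identical spec + seed gives an identical image.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(size = c(96, 128), n_straight_lines = 0L,
                       n_curves = 0L, base_hue = 0.3, hue_jitter = 0.05,
                       base_sat = 0.4, sat_gradient_amplitude = 0,
                       base_bright = 0.55, texture_noise_sd = 0.03,
                       seed = NULL) {
  stopifnot(length(size) == 2, all(size >= 8),
            n_straight_lines >= 0, n_curves >= 0,
            base_hue >= 0, base_hue <= 1, hue_jitter >= 0, hue_jitter <= 1,
            base_sat >= 0, base_sat <= 1,
            sat_gradient_amplitude >= 0, sat_gradient_amplitude <= 1,
            base_bright >= 0, base_bright <= 1, texture_noise_sd >= 0)
  structure(list(size = as.integer(size),
                 n_straight_lines = as.integer(n_straight_lines),
                 n_curves = as.integer(n_curves),
                 base_hue = base_hue, hue_jitter = hue_jitter,
                 base_sat = base_sat,
                 sat_gradient_amplitude = sat_gradient_amplitude,
                 base_bright = base_bright,
                 texture_noise_sd = texture_noise_sd, seed = seed),
            class = "scene_spec")
}

#' @describeIn scene_spec a man-made-looking preset: a grid of straight
#'   segments on a flat, desaturated, noise-free field (low hue diversity).
#' @export
urban_scene_spec <- function(size = c(96, 128), seed = NULL) {
  scene_spec(size = size, n_straight_lines = 14L, n_curves = 0L,
             base_hue = 0.08, hue_jitter = 0, base_sat = 0.15,
             sat_gradient_amplitude = 0, base_bright = 0.62,
             texture_noise_sd = 0, seed = seed)
}

#' @describeIn scene_spec a nature-looking preset: curved contours over a
#'   green, saturation-graded, textured field.
#' @export
nature_scene_spec <- function(size = c(96, 128), seed = NULL) {
  scene_spec(size = size, n_straight_lines = 0L, n_curves = 10L,
             base_hue = 0.33, hue_jitter = 0.06, base_sat = 0.45,
             sat_gradient_amplitude = 0.3, base_bright = 0.55,
             texture_noise_sd = 0.04, seed = seed)
}

# Raster of one straight segment at 0/45/90/135 degrees, n_pixels = len.
.raster_line <- function(H, W, len, angle) {
  if (angle == 0) {
    r0 <- sample(2:(H - 1), 1); c0 <- sample(1:(W - len + 1), 1)
    cbind(r0, c0:(c0 + len - 1))
  } else if (angle == 90) {
    c0 <- sample(2:(W - 1), 1); r0 <- sample(1:(H - len + 1), 1)
    cbind(r0:(r0 + len - 1), c0)
  } else if (angle == 45) {
    r0 <- sample(1:(H - len + 1), 1); c0 <- sample(1:(W - len + 1), 1)
    t <- 0:(len - 1); cbind(r0 + t, c0 + t)
  } else {
    r0 <- sample(1:(H - len + 1), 1); c0 <- sample(len:W, 1)
    t <- 0:(len - 1); cbind(r0 + t, c0 - t)
  }
}

# Raster of one circle arc (curvature bounded away from zero).
.raster_arc <- function(H, W) {
  for (try in 1:50) {
    # radius capped at 18: larger rasterized circles develop exactly
    # collinear flat runs of >= 10 px at their cardinal extremes, which the
    # straightness criterion (correctly) classifies as straight segments
    radius <- stats::runif(1, 8, 18)
    cy <- stats::runif(1, 1 + radius * 0.2, H - radius * 0.2)
    cx <- stats::runif(1, 1 + radius * 0.2, W - radius * 0.2)
    a0 <- stats::runif(1, 0, 2 * pi)
    span <- stats::runif(1, pi, 2 * pi)
    ang <- seq(a0, a0 + span, by = 0.5 / radius)
    rr <- round(cy + radius * sin(ang)); cc <- round(cx + radius * cos(ang))
    keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    coords <- unique(cbind(rr[keep], cc[keep]))
    if (nrow(coords) >= 25) return(coords)
  }
  stop("could not place a curved contour; image too small")
}

#' Generate a synthetic scene image
#'
#' Renders the HSV base field described by the spec, draws the requested
#' straight segments and curved contours in contrasting brightness, and
#' converts to 8-bit RGB. Deterministic for a given spec (including its
#' seed).
#'
#' @param spec a [scene_spec()].
#' @return A [scene_image()] with attribute `primitives`, a tibble listing
#'   each drawn primitive (`type`, `n_pixels`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  n_prim <- spec$n_straight_lines + spec$n_curves
  if (n_prim > 0 && min(H, W) < 48) {
    stop("image too small to place contours (need min dimension >= 48)")
  }
  if (n_prim > floor(H * W / 250)) {
    stop("contour count infeasible for image size")
  }
  render <- function() {
    clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)
    h <- clamp(spec$base_hue +
                 stats::runif(H * W, -spec$hue_jitter, spec$hue_jitter))
    grad <- spec$sat_gradient_amplitude *
      (matrix(seq_len(H), H, W) - (H + 1) / 2) / (H / 2)
    s <- clamp(spec$base_sat + as.vector(grad))
    v <- clamp(spec$base_bright +
                 stats::rnorm(H * W, 0, spec$texture_noise_sd), 0.02, 1)
    v <- matrix(v, H, W)
    # contrasting brightness for drawn contours
    pv <- if (spec$base_bright >= 0.5) max(0.05, spec$base_bright - 0.5) else
      min(0.95, spec$base_bright + 0.5)
    prim <- list()
    if (spec$n_straight_lines > 0) {
      for (i in seq_len(spec$n_straight_lines)) {
        angle <- sample(c(0, 90), 1)
        max_len <- if (angle == 0) W - 2 else H - 2
        len <- sample(40:max(40, min(max_len, 90)), 1)
        coords <- .raster_line(H, W, len, angle)
        v[coords] <- pv
        prim[[length(prim) + 1]] <-
          tibble::tibble(type = "line", n_pixels = nrow(coords))
      }
    }
    if (spec$n_curves > 0) {
      for (i in seq_len(spec$n_curves)) {
        coords <- .raster_arc(H, W)
        v[coords] <- pv
        prim[[length(prim) + 1]] <-
          tibble::tibble(type = "curve", n_pixels = nrow(coords))
      }
    }
    cols <- grDevices::hsv(h, s, as.vector(v))
    rgb <- grDevices::col2rgb(cols)
    px <- array(0L, dim = c(H, W, 3))
    px[, , 1] <- matrix(rgb[1, ], H, W)
    px[, , 2] <- matrix(rgb[2, ], H, W)
    px[, , 3] <- matrix(rgb[3, ], H, W)
    img <- scene_image(px)
    attr(img, "primitives") <- if (length(prim)) dplyr::bind_rows(prim) else
      tibble::tibble(type = character(), n_pixels = integer())
    img
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, render()) else render()
}
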