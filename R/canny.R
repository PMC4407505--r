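#' Edge detection configuration
#'
#' Parameters of the weighted dual-threshold Canny detector. The base
#' threshold pair is data-driven: the high threshold is the smallest gradient
#' magnitude above the `percentile` quantile of the nonzero gradient
#' magnitudes, and the low threshold is `low_ratio` times the high one. Canny
#' is then run twice, with both thresholds scaled by `scale_sensitive`
#' (detects faint edges) and by `scale_insensitive` (keeps only salient
#' edges). This mirrors the common toolbox heuristic of deriving a
#' "reasonable" pair from the gradient-magnitude distribution and then
#' shifting it 20% down and 60% up; the exact stock heuristic is not
#' published, so the percentile rule here is a documented approximation.
#'
#' @param sigma Gaussian smoothing scale in pixels for the
#'   derivative-of-Gaussian gradient.
#' @param percentile quantile of the gradient-magnitude distribution (over
#'   all pixels) anchoring the base high threshold.
#' @param low_ratio low threshold as a fraction of the high threshold.
#' @param scale_sensitive,scale_insensitive multipliers applied to the base
#'   threshold pair for the two detection passes.
#' @param base_thresholds optional explicit base pair `c(low, high)` (on
#'   gradient-magnitude scale, intensities in `[0, 1]`), bypassing the
#'   data-driven heuristic.
#' @return A list of class `edge_config`.
#' @export
edge_config <- function(sigma = 1.4, percentile = 0.7, low_ratio = 0.4,
                        scale_sensitive = 0.8, scale_insensitive = 1.6,
                        base_thresholds = NULL) {
  stopifnot(sigma > 0, percentile > 0, percentile < 1,
            low_ratio > 0, low_ratio < 1,
            scale_sensitive > 0, scale_insensitive > scale_sensitive)
  if (!is.null(base_thresholds)) {
    stopifnot(length(base_thresholds) == 2, all(base_thresholds > 0),
              base_thresholds[1] < base_thresholds[2])
  }
  structure(list(sigma = sigma, percentile = percentile, low_ratio = low_ratio,
                 scale_sensitive = scale_sensitive,
                 scale_insensitive = scale_insensitive,
                 base_thresholds = base_thresholds),
            class = "edge_config")
}

# 1-D Gaussian and derivative-of-Gaussian kernels (radius 3*sigma).
.gauss_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  list(g = g / sum(g), dg = -x / sigma^2 * exp(-x^2 / (2 * sigma^2)))
}

# Separable 1-D convolution along rows (dir = "y") or columns (dir = "x"),
# with replicate padding.
.conv1d <- function(m, k, dir = c("x", "y")) {
  dir <- match.arg(dir)
  r <- (length(k) - 1L) %/% 2L
  if (dir == "y") return(t(.conv1d(t(m), k, "x")))
  W <- ncol(m)
  mp <- m[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  out <- matrix(0, nrow(m), W)
  for (i in seq_along(k)) {
    out <- out + k[i] * mp[, i:(i + W - 1L), drop = FALSE]
  }
  out
}

# Shift a matrix by (di, dj), zero-filling exposed borders:
# out[i, j] = m[i + di, j + dj].
.shift <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  si <- seq_len(H) + di; sj <- seq_len(W) + dj
  oki <- si >= 1 & si <= H; okj <- sj >= 1 & sj <= W
  out[oki, okj] <- m[si[oki], sj[okj]]
  out
}

# Non-maximum suppression with gradient direction quantized to 4 sectors.
.nms_mask <- function(mag, gx, gy) {
  theta <- (atan2(gy, gx) * 180 / pi) %% 180
  sector <- (floor((theta + 22.5) / 45)) %% 4
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    d <- offs[[s + 1L]]
    n1 <- .shift(mag, d[1], d[2])
    n2 <- .shift(mag, -d[1], -d[2])
    sel <- sector == s
    keep[sel] <- mag[sel] >= n1[sel] & mag[sel] > n2[sel]
  }
  keep & mag > 0
}

# One Canny detection pass: double thresholding + hysteresis by
# connected-component tracking (8-connectivity).
.canny_detect <- function(mag, nms, low, high) {
  weak <- nms & mag >= low
  strong <- weak & mag >= high
  if (!any(strong)) return(matrix(FALSE, nrow(mag), ncol(mag)))
  labels <- label_components(weak, 8L)
  keep <- unique(labels[strong])
  weak & matrix(labels %in% keep, nrow(mag), ncol(mag))
}

#' Weighted dual-threshold Canny edge map
#'
#' Detects edges twice, once at a high-sensitivity threshold pair (base
#' thresholds scaled down) and once at a low-sensitivity pair (scaled up),
#' and weights each pixel 1 if it survives the low-sensitivity (salient) pass,
#' 0.5 if it is detected only at high sensitivity (faint), and 0 otherwise.
#' Pixels at weight 1 are always a subset of the high-sensitivity detection
#' set. A constant image yields an all-zero map.
#'
#' @param gray a `gray_image` from [to_grayscale()] (or any numeric matrix of
#'   intensities on 0-255).
#' @param cfg an [edge_config()].
#' @return An `edge_map`: list with `weights` (`H x W` matrix over
#'   `{0, 0.5, 1}`), `gx`, `gy` (derivative-of-Gaussian gradients), and
#'   `thresholds` (`base`, `sensitive`, `insensitive` pairs `c(low, high)`).
#' @export
weighted_canny <- function(gray, cfg = edge_config()) {
  stopifnot(inherits(cfg, "edge_config"))
  m <- unclass(gray)
  attr(m, "histogram") <- NULL
  storage.mode(m) <- "double"
  m <- m / 255
  k <- .gauss_kernels(cfg$sigma)
  gx <- .conv1d(.conv1d(m, k$dg, "x"), k$g, "y")
  gy <- .conv1d(.conv1d(m, k$dg, "y"), k$g, "x")
  mag <- sqrt(gx^2 + gy^2)

  empty <- function(thr) {
    structure(list(weights = matrix(0, nrow(m), ncol(m)), gx = gx, gy = gy,
                   thresholds = thr), class = "edge_map")
  }
  # gradient magnitudes below this floor are cancellation dust from the
  # separable convolution of flat regions, not image structure
  nz <- mag[mag > 1e-6]
  if (length(nz) == 0) return(empty(NULL))

  if (is.null(cfg$base_thresholds)) {
    # quantile over all pixels (dust-floored to zero), as in the stock
    # "fraction of pixels that are not edges" heuristic
    q <- stats::quantile(ifelse(mag > 1e-6, mag, 0), cfg$percentile,
                         names = FALSE)
    above <- nz[nz > q]
    high <- if (length(above)) min(above) else max(nz)
    base <- c(low = cfg$low_ratio * high, high = high)
  } else {
    base <- c(low = cfg$base_thresholds[1], high = cfg$base_thresholds[2])
  }
  thr <- list(base = base,
              sensitive = base * cfg$scale_sensitive,
              insensitive = base * cfg$scale_insensitive)

  nms <- .nms_mask(mag, gx, gy)
  faint <- .canny_detect(mag, nms, thr$sensitive[1], thr$sensitive[2])
  salient <- .canny_detect(mag, nms, thr$insensitive[1], thr$insensitive[2])
  weights <- ifelse(salient, 1, ifelse(faint, 0.5, 0))
  structure(list(weights = weights, gx = gx, gy = gy, thresholds = thr),
            class = "edge_map")
}

#' Edge density of a weighted edge map
#'
#' Sum of all pixel edge weights (0, 0.5 faint, 1 salient) divided by the
#' total number of pixels, so the statistic is normalized to image size.
#'
#' @param edges an `edge_map` from [weighted_canny()].
#' @return Edge density in `[0, 1]`.
#' @export
edge_density <- function(edges) {
  stopifnot(inherits(edges, "edge_map"))
  sum(edges$weights) / length(edges$weights)
}
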