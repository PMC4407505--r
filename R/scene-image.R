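#' Scene images
#'
#' A scene image is an 8-bit RGB raster stored as an integer `H x W x 3` array
#' with values in 0-255. [scene_image()] validates and tags such an array;
#' [read_scene_image()] loads one from a PNG (or JPEG, when \pkg{EBImage} is
#' installed) file, dropping any alpha channel with a warning.
#'
#' @param pixels numeric or integer `H x W x 3` array, values in 0-255.
#' @return A `scene_image`: an integer array with dimensions `c(H, W, 3)`.
#' @examples
#' img <- scene_image(array(128L, dim = c(16, 16, 3)))
#' dim(img)
#' @export
scene_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("a scene image must be an H x W x 3 array (3 channels)", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 8 || d[2] < 8) {
    stop("scene images must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("scene_image", class(array(0L))))
}

#' @param path file path to a PNG or JPEG image.
#' @rdname scene_image
#' @export
read_scene_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package", call. = FALSE)
    }
    px <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores x as the first dimension; transpose back to row = y.
    px <- aperm(px, c(2, 1, seq_len(length(dim(px)))[-(1:2)]))
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(px)) == 2) px <- array(px, dim = c(dim(px), 1))
  if (dim(px)[3] == 4) {
    warning("alpha channel dropped from ", basename(path))
    px <- px[, , 1:3, drop = FALSE]
  }
  if (dim(px)[3] == 1) px <- px[, , c(1, 1, 1), drop = FALSE]
  scene_image(round(px * 255))
}

#' Write a scene image to a PNG file
#'
#' @param image a [scene_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scene_image <- function(image, path) {
  image <- scene_image(unclass(image))
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Convert a scene image to 8-bit grayscale
#'
#' Uses ITU-R BT.601 luma weights, `0.2989 R + 0.5870 G + 0.1140 B`, rounded
#' to the nearest integer and clipped to 0-255. The result carries the 256-bin
#' intensity histogram (as bin probabilities) used by [image_entropy()].
#'
#' @param image a [scene_image()].
#' @return A `gray_image`: integer `H x W` matrix with attribute `histogram`,
#'   a length-256 vector of bin probabilities summing to 1 (bin `n` counts
#'   pixels of intensity `n - 1`).
#' @examples
#' g <- to_grayscale(scene_image(array(255L * c(1, 0, 0), dim = c(8, 8, 3))))
#' g[1, 1]  # round(0.2989 * 255) = 76
#' @export
to_grayscale <- function(image) {
  image <- scene_image(unclass(image))
  g <- 0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
  g <- pmin(pmax(round(g), 0), 255)
  storage.mode(g) <- "integer"
  h <- tabulate(as.vector(g) + 1L, nbins = 256L)
  structure(g, histogram = h / sum(h), class = c("gray_image", "matrix"))
}

#' Shannon entropy of a grayscale image
#'
#' Entropy in bits of the 256-bin intensity histogram,
#' `-sum(p_n log2 p_n)` with `0 log2 0 = 0`. Ranges from 0 (a single
#' occupied bin) to 8 (all 256 intensities equally frequent); higher values
#' indicate a more uniform intensity distribution.
#'
#' @param gray a `gray_image` from [to_grayscale()], or a 256-bin probability
#'   vector.
#' @return Entropy in bits, a scalar in `[0, 8]`.
#' @export
image_entropy <- function(gray) {
  p <- if (is.numeric(gray) && is.null(dim(gray)) && length(gray) == 256) {
    gray
  } else {
    attr(gray, "histogram")
  }
  if (is.null(p)) stop("gray must be a gray_image or a 256-bin histogram")
  stopifnot(abs(sum(p) - 1) < 1e-9, all(p >= 0))
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' HSV channel statistics of a scene image
#'
#' Converts the image to HSV (hexcone model, each channel on `[0, 1]`) and
#' returns the per-channel mean and standard deviation over all pixels. Hue is
#' treated as a linear variable on `[0, 1]`, not circularly, matching the
#' stock channel-statistics convention of common image toolboxes.
#'
#' @param image a [scene_image()].
#' @param sd_type `"population"` (divide by N, the default) or `"sample"`.
#' @return Named list with `hue`, `sd_hue`, `sat`, `sd_sat`, `bright`,
#'   `sd_bright`, all in `[0, 1]`.
#' @export
color_statistics <- function(image, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  image <- scene_image(unclass(image))
  rgb <- matrix(as.numeric(image), ncol = 3)  # columns R, G, B
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  dev <- function(x) {
    v <- mean((x - mean(x))^2)
    if (sd_type == "sample") v <- v * length(x) / (length(x) - 1)
    sqrt(v)
  }
  list(
    hue = mean(hsv["h", ]), sd_hue = dev(hsv["h", ]),
    sat = mean(hsv["s", ]), sd_sat = dev(hsv["s", ]),
    bright = mean(hsv["v", ]), sd_bright = dev(hsv["v", ])
  )
}
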