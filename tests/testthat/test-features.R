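test_that("grayscale conversion uses BT.601 luma and builds a unit histogram", {
  expect_equal(to_grayscale(solid_image(128, 128, 128))[1, 1], 128L)
  expect_equal(to_grayscale(solid_image(255, 0, 0))[1, 1], 76L)  # round(.2989*255)

  px <- array(0L, dim = c(8, 8, 3))
  px[1, 1, ] <- 255L  # one white pixel among 63 black
  h <- attr(to_grayscale(scene_image(px)), "histogram")
  expect_equal(sum(h), 1)
  expect_equal(h[1], 63 / 64)
  expect_equal(h[256], 1 / 64)

  expect_error(scene_image(array(0L, dim = c(8, 8, 2))), "3 channels")
})

test_that("color statistics match hand-computed HSV values", {
  red <- color_statistics(solid_image(255, 0, 0))
  expect_equal(unlist(red),
               c(hue = 0, sd_hue = 0, sat = 1, sd_sat = 0,
                 bright = 1, sd_bright = 0))

  gray <- color_statistics(solid_image(128, 128, 128))
  expect_equal(gray$sat, 0)
  expect_equal(gray$bright, 128 / 255)
  expect_equal(gray$sd_hue + gray$sd_sat + gray$sd_bright, 0)

  # half pure red, half pure green: hues {0, 1/3}, linear mean 1/6,
  # population SD 1/6; saturation constant at 1
  px <- array(0L, dim = c(8, 8, 3))
  px[1:4, , 1] <- 255L
  px[5:8, , 2] <- 255L
  rg <- color_statistics(scene_image(px))
  expect_equal(rg$hue, 1 / 6)
  expect_equal(rg$sd_hue, 1 / 6)
  expect_equal(rg$sat, 1)
  expect_equal(rg$sd_sat, 0)
})

test_that("entropy matches closed forms at 0, 1 and 8 bits", {
  expect_equal(image_entropy(to_grayscale(solid_image(77, 77, 77))), 0)

  px <- array(0L, dim = c(8, 8, 3))
  px[1:4, , ] <- 255L  # two intensity values, p = 0.5 each
  expect_equal(image_entropy(to_grayscale(scene_image(px))), 1)

  # all 256 intensities equally frequent
  g <- matrix(rep(0:255, each = 4), 32, 32)
  px <- array(rep(as.integer(g), 3), dim = c(32, 32, 3))
  expect_equal(image_entropy(to_grayscale(scene_image(px))), 8)
})

test_that("edge density is the normalized weighted pixel sum", {
  mk <- function(w) structure(list(weights = w), class = "edge_map")
  w <- matrix(0, 100, 100)
  expect_equal(edge_density(mk(w)), 0)
  w[1, 1:100] <- 1
  expect_equal(edge_density(mk(w)), 0.01)
  w[1, 1:100] <- 0.5
  expect_equal(edge_density(mk(w)), 0.005)
})

test_that("weighted Canny handles constant images and assigns dual weights", {
  em <- weighted_canny(to_grayscale(solid_image(90, 90, 90)))
  expect_true(all(em$weights == 0))
  expect_equal(edge_density(em), 0)

  # strong vertical step: detected at weight 1 in both passes, and matches a
  # direct detection run at the low-sensitivity (insensitive) thresholds
  px <- array(0L, dim = c(100, 100, 3)); px[, 51:100, ] <- 255L
  em <- weighted_canny(to_grayscale(scene_image(px)))
  expect_true(sum(em$weights == 1) >= 90)   # one ridge ~ column height
  expect_true(all(em$weights %in% c(0, 1)))  # nothing faint in a clean step
  # salient pixels are a subset of the sensitive-pass detections
  expect_true(all(em$weights[em$weights == 1] > 0))

  # two-amplitude image with explicit base thresholds: the faint line's
  # gradient (~0.023) lies between the sensitive high (0.8 x 0.02) and the
  # insensitive high (1.6 x 0.02) -> weight 0.5; the strong step -> weight 1
  px <- array(60L, dim = c(100, 100, 3))
  px[, 51:100, ] <- 200L       # strong step at column 50
  px[26:75, 10, ] <- 75L       # faint vertical line
  g2 <- to_grayscale(scene_image(px))
  cfg <- edge_config(base_thresholds = c(0.008, 0.02))
  em <- weighted_canny(g2, cfg)
  faint_cols <- unique(which(em$weights == 0.5, arr.ind = TRUE)[, 2])
  expect_true(length(faint_cols) > 0)
  expect_true(all(abs(faint_cols - 10) <= 2))
  salient_cols <- unique(which(em$weights == 1, arr.ind = TRUE)[, 2])
  expect_true(all(abs(salient_cols - 50) <= 2))

  # oracle: the weight-1 set equals an independent detection pass run
  # directly at the insensitive (1.6-scaled) thresholds
  cfg_or <- edge_config(scale_sensitive = 1.6, scale_insensitive = 3.2,
                        base_thresholds = c(0.008, 0.02))
  em_or <- weighted_canny(g2, cfg_or)
  expect_identical(em$weights == 1, em_or$weights > 0)
})

test_that("edge detection set shrinks as thresholds scale up", {
  img <- generate_scene(nature_scene_spec(seed = 5))
  g <- to_grayscale(img)
  em1 <- weighted_canny(g, edge_config())
  # same base pair, everything scaled 1.5x up
  em2 <- weighted_canny(g, edge_config(scale_sensitive = 0.8 * 1.5,
                                       scale_insensitive = 1.6 * 1.5))
  expect_lte(edge_density(em2), edge_density(em1))
  # weight-1 pixels always lie inside the faint-or-salient detection set
  expect_true(all(em1$weights[em1$weights == 1] > 0.5))
})

test_that("feature extraction is deterministic, size-normalized and handles degenerate scenes", {
  f0 <- extract_features(solid_image(120, 120, 120, 32, 32))
  expect_equal(f0$entropy, 0)
  expect_equal(f0$ed, 0)
  expect_equal(f0$sed, 0)
  expect_true(is.na(f0$der))
  expect_equal(f0$sat, 0)

  img <- generate_scene(urban_scene_spec(seed = 2))
  f1 <- extract_features(img)
  f2 <- extract_features(img)
  expect_identical(f1, f2)

  # tiling 2x2 leaves the per-pixel densities nearly unchanged
  px <- unclass(img)
  big <- array(0L, dim = c(2 * dim(px)[1], 2 * dim(px)[2], 3))
  for (a in 0:1) for (b in 0:1) {
    big[a * dim(px)[1] + seq_len(dim(px)[1]),
        b * dim(px)[2] + seq_len(dim(px)[2]), ] <- px
  }
  ft <- extract_features(scene_image(big))
  expect_lt(abs(ft$ed - f1$ed) / f1$ed, 0.02)
  expect_lt(abs(ft$sed - f1$sed) / f1$sed, 0.02)
})

test_that("disorganized edge ratio splits straight and curved edge mass", {
  # straight lines only -> DER near 0
  img <- drawn_image(rbind(cbind(30, 20:100), cbind(60, 15:95)))
  em <- weighted_canny(to_grayscale(img))
  se <- straight_edges(em)
  expect_lt(disorganized_edge_ratio(em, se), 0.15)

  # one straight line plus one circle of equal drawn mass -> DER near 0.5
  ang <- seq(0, 2 * pi, length.out = 400)
  circ <- unique(cbind(round(48 + 16 * sin(ang)), round(60 + 16 * cos(ang))))
  line_len <- nrow(circ)  # match pixel counts
  img <- drawn_image(rbind(cbind(10, 5 + seq_len(line_len)), circ))
  em <- weighted_canny(to_grayscale(img))
  se <- straight_edges(em)
  der <- disorganized_edge_ratio(em, se)
  expect_gt(der, 0.35)
  expect_lt(der, 0.65)

  # circle only -> DER = 1 (no straight component)
  img <- drawn_image(circ)
  em <- weighted_canny(to_grayscale(img))
  se <- straight_edges(em)
  expect_equal(disorganized_edge_ratio(em, se), 1)

  # no edges at all -> undefined ratio
  em0 <- weighted_canny(to_grayscale(solid_image(50, 50, 50)))
  expect_error(disorganized_edge_ratio(em0, straight_edges(em0)),
               class = "scenestats_undefined_ratio")
})
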