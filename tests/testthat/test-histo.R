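flat_image <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("tile_image produces grid tiles and honours the mask rule", {
  img <- flat_image(300, 300, c(0.5, 0.5, 0.5))
  expect_length(tile_image(img, side = 100), 9)
  expect_length(tile_image(img, side = 300), 1)
  # partial edge tiles discarded
  expect_length(tile_image(flat_image(250, 199, c(1, 1, 1)), side = 100), 2)
  expect_warning(out <- tile_image(flat_image(50, 50, c(1, 1, 1)), side = 100),
                 "smaller")
  expect_length(out, 0)
  # mask: keep only tiles with >= 50% coverage, checked by pixel count
  mask <- matrix(0, 300, 300)
  mask[1:150, 1:300] <- 1           # top half fully covered
  kept <- tile_image(img, mask, side = 100)
  frac <- sapply(1:3, function(i) sapply(1:3, function(j)
    mean(mask[((i - 1) * 100 + 1):(i * 100), ((j - 1) * 100 + 1):(j * 100)])))
  expect_length(kept, sum(frac >= 0.5))
})

two_stain_tile <- function(seed = 15, n = 64) {
  stains <- cbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  stains <- sweep(stains, 2, sqrt(colSums(stains^2)), "/")
  set.seed(seed)
  c1 <- runif(n * n, 0, 1.2)
  c2 <- runif(n * n, 0, 1.2)
  pure <- sample.int(n * n, 400)
  c2[pure[1:200]] <- 0
  c1[pure[201:400]] <- 0
  od <- cbind(c1, c2) %*% t(stains)
  img <- array((256 * 10^(-od) - 1) / 255, dim = c(n, n, 3))
  img[img < 0] <- 0
  list(img = img, stains = stains)
}

test_that("macenko normalization is near-identity against itself", {
  tile <- two_stain_tile()$img
  out <- macenko_normalize(tile, tile)
  frac_close <- mean(abs(out - tile) * 255 <= 2)
  expect_gte(frac_close, 0.99)
})

test_that("macenko recovers known stain directions within 5 degrees", {
  # synthesize a two-stain image from known stain vectors, with
  # concentrations spanning pure-stain extremes
  ts <- two_stain_tile(seed = 16)
  img <- ts$img
  stains <- ts$stains
  est <- estimate_stain_matrix(img)
  angle <- function(u, v) acos(pmin(1, sum(u * v))) * 180 / pi
  expect_lt(angle(est[, 1], stains[, 1]), 5)
  expect_lt(angle(est[, 2], stains[, 2]), 5)
})

test_that("all-white tiles pass through with a warning", {
  white <- flat_image(64, 64, c(1, 1, 1))
  ref <- flat_image(64, 64, c(0.5, 0.4, 0.6))
  expect_warning(out <- macenko_normalize(white, ref), "foreground")
  expect_identical(out, white)
})

test_that("multilevel_otsu separates well-defined classes", {
  set.seed(17)
  x <- c(rnorm(500, 0.1, 0.02), rnorm(500, 0.5, 0.02), rnorm(500, 0.9, 0.02))
  t2 <- multilevel_otsu(x, 2)
  expect_true(t2 > 0.15 && t2 < 0.85)
  t3 <- multilevel_otsu(x, 3)
  expect_true(t3[1] > 0.15 && t3[1] < 0.45)
  expect_true(t3[2] > 0.55 && t3[2] < 0.85)
})

test_that("segment_nuclei finds rendered nuclei and applies size filters", {
  set.seed(18)
  tile <- render_nucleus_tile(10, small_image_params())
  labels <- segment_nuclei(tile$img)
  expect_equal(max(labels), 10)
  # blank tile
  blank <- flat_image(128, 128, c(0.91, 0.72, 0.80))
  expect_equal(max(segment_nuclei(blank)), 0)
  # a 5 um^2 speck is removed by the area filter (area < 10 um^2)
  speck <- flat_image(128, 128, c(0.91, 0.72, 0.80))
  speck[60:63, 60:64, 1] <- 0.36
  speck[60:63, 60:64, 2] <- 0.28
  speck[60:63, 60:64, 3] <- 0.55
  expect_equal(max(segment_nuclei(speck)), 0)
})

test_that("nucleus_features matches analytic geometry and colours", {
  # rendered circle of radius 10 um = 20 px at 0.5 um/px
  img <- flat_image(128, 128, c(1, 1, 1))
  labels <- matrix(0L, 128, 128)
  center <- c(64, 64)
  for (i in 1:128) for (j in 1:128) {
    if ((i - center[1])^2 + (j - center[2])^2 <= 20^2) labels[i, j] <- 1L
  }
  img[, , 1][labels == 1] <- 1   # pure red nucleus
  img[, , 2][labels == 1] <- 0
  img[, , 3][labels == 1] <- 0
  f <- nucleus_features(labels, img, mpp = 0.5)
  expect_equal(f$area, 100 * pi, tolerance = 0.05)
  expect_equal(f$rmean, 255)
  expect_equal(f$gmean, 0)
  expect_equal(f$bmean, 0)
  expect_gt(f$circularity, 0.85)
  expect_gt(f$solidity, 0.95)
  expect_equal(f$dist_mean, 0)  # single nucleus: distances are zero

  # two nuclei 100 px = 50 um apart
  labels2 <- matrix(0L, 128, 228)
  img2 <- flat_image(128, 228, c(1, 1, 1))
  for (i in 1:128) for (j in 1:228) {
    if ((i - 64)^2 + (j - 60)^2 <= 10^2) labels2[i, j] <- 1L
    if ((i - 64)^2 + (j - 160)^2 <= 10^2) labels2[i, j] <- 2L
  }
  f2 <- nucleus_features(labels2, img2, mpp = 0.5)
  expect_equal(f2$dist_mean, c(50, 50))
  expect_equal(f2$dist_max, c(50, 50))
  expect_equal(f2$dist_min, c(50, 50))
})

test_that("image_level_features yields 150 finite values with unit bins", {
  set.seed(19)
  tile <- render_nucleus_tile(20, small_image_params())
  rec <- nucleus_features(segment_nuclei(tile$img), tile$img, 0.5)
  v <- image_level_features(rec)
  expect_length(v, 150)
  expect_true(all(is.finite(v)))
  for (f in c("area", "rmean", "dist_mean")) {
    expect_equal(sum(v[paste0(f, "_bin", 1:10)]), 1)
  }
  expect_length(histogram_feature_names(), 100)
  expect_true(all(histogram_feature_names() %in% names(v)))
  expect_error(image_level_features(rec[0, ]), "empty")
})

test_that("degenerate and uniform distributions follow the stated conventions", {
  rec <- data.frame(tile_id = "t", label = 1:5)
  for (f in c("area", "circularity", "solidity", "rmean", "gmean", "bmean",
              "intensity_std", "dist_mean", "dist_max", "dist_min")) {
    rec[[f]] <- 100  # all identical
  }
  v <- image_level_features(rec)
  expect_equal(unname(v["area_std"]), 0)
  expect_equal(unname(v["area_skewness"]), 0)
  expect_equal(unname(v["area_kurtosis"]), 0)
  expect_equal(unname(v["area_entropy"]), 0)
  expect_equal(sum(v[paste0("area_bin", 1:10)] == 1), 1)
  # uniform across bins maximises entropy at log2(10)
  rec10 <- rec[rep(1, 10), ]
  rec10$area <- seq(25, 475, by = 50)  # one value per bin of [0, 500]
  v10 <- image_level_features(rec10)
  expect_equal(unname(v10["area_entropy"]), log2(10))
})

test_that("distribution statistics match an independent moment oracle", {
  skip_if_not_installed("e1071")
  set.seed(20)
  x <- rlnorm(500, meanlog = 3, sdlog = 0.4)
  rec <- data.frame(tile_id = "t", label = seq_along(x))
  for (f in c("area", "circularity", "solidity", "rmean", "gmean", "bmean",
              "intensity_std", "dist_mean", "dist_max", "dist_min")) {
    rec[[f]] <- x
  }
  v <- image_level_features(rec)
  expect_equal(unname(v["area_mean"]), mean(x))
  expect_equal(unname(v["area_std"]), sd(x))
  expect_equal(unname(v["area_skewness"]), e1071::skewness(x, type = 1),
               tolerance = 1e-9)
  expect_equal(unname(v["area_kurtosis"]), e1071::kurtosis(x, type = 1),
               tolerance = 1e-9)
})

test_that("focus_pair_correlation behaves on identity, negation and errors", {
  set.seed(21)
  v <- rnorm(150)
  expect_equal(focus_pair_correlation(v, v), 1.0)
  expect_equal(focus_pair_correlation(v, -v), -1.0)
  expect_error(focus_pair_correlation(rep(1, 150), v), "constant")
  # standardization drops zero-variance features
  center <- rep(0, 150)
  scale <- c(0, rep(1, 149))
  expect_equal(focus_pair_correlation(v, v, center, scale), 1.0)
})

test_that("IM focus pairs correlate more strongly than MO pairs", {
  p <- small_image_params(side = 224, n_range = c(8, 18))
  focus_vec <- function(tl) {
    lab <- segment_nuclei(tl$img, mpp = p$mpp)
    image_level_features(nucleus_features(lab, tl$img, p$mpp))
  }
  set.seed(22)
  n_per <- 15
  vecs <- list()
  pats <- character(0)
  for (i in seq_len(2 * n_per)) {
    pat <- if (i <= n_per) "IM" else "MO"
    sp <- simulate_focus_pair_images(pat, p)
    vecs[[2 * i - 1]] <- focus_vec(sp$tile_a)
    vecs[[2 * i]] <- focus_vec(sp$tile_b)
    pats <- c(pats, pat)
  }
  fmat <- do.call(rbind, vecs)
  st <- cohort_feature_stats(fmat)
  cors <- vapply(seq_len(2 * n_per), function(i)
    focus_pair_correlation(fmat[2 * i - 1, ], fmat[2 * i, ],
                           st$center, st$scale), numeric(1))
  mw <- mann_whitney(cors[pats == "IM"], cors[pats == "MO"])
  expect_gt(mean(cors[pats == "IM"]), mean(cors[pats == "MO"]))
  expect_lt(mw$p_value, 0.05)
})
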