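# H&E tile processing: tiling, Macenko stain normalization, multilevel-
# threshold nucleus segmentation, nucleus-level morphometry and the
# image-level histogram/statistics features used for inter-focus
# correlation.
#
# Tiles are plain R arrays [height, width, 3] with values in [0, 1]
# (png::readPNG convention); physical scale enters only through the
# microns-per-pixel argument (default 0.5).

#' Cut an image into non-overlapping tiles
#'
#' Grid tiles of `side` x `side` pixels fully inside the image; partial
#' edge tiles are discarded. When a binary cancer-region mask is supplied,
#' only tiles with at least half their pixels inside the mask are kept.
#'
#' @param image RGB array `[h, w, 3]`.
#' @param mask optional binary matrix `[h, w]` (1 = cancer region).
#' @param side tile side in pixels (default 2048).
#' @return list of RGB arrays; empty (with a warning) if the image is
#'   smaller than one tile.
#' @export
tile_image <- function(image, mask = NULL, side = 2048) {
  h <- dim(image)[1]
  w <- dim(image)[2]
  if (h < side || w < side) {
    warning("image smaller than one tile; no tiles produced")
    return(list())
  }
  if (!is.null(mask) && !all(dim(mask)[1:2] == c(h, w))) {
    stop("mask dimensions must match the image")
  }
  tiles <- list()
  for (i in seq_len(h %/% side)) {
    for (j in seq_len(w %/% side)) {
      rows <- ((i - 1) * side + 1):(i * side)
      cols <- ((j - 1) * side + 1):(j * side)
      if (!is.null(mask) && mean(mask[rows, cols]) < 0.5) next
      tiles[[length(tiles) + 1]] <- image[rows, cols, , drop = FALSE]
    }
  }
  tiles
}

#' Optical-density transform of an 8-bit RGB image
#'
#' `OD = -log10((I + 1) / 256)` per channel, with `I` the 0-255 intensity.
#'
#' @param img RGB array in `[0, 1]`.
#' @return array of optical densities, same shape.
#' @export
rgb_to_od <- function(img) {
  -log10((img * 255 + 1) / 256)
}

od_to_rgb <- function(od) {
  out <- (256 * 10^(-od) - 1) / 255
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

# Standard H&E stain OD vectors (hematoxylin, eosin), unit length.
HE_REFERENCE_STAINS <- local({
  m <- cbind(h = c(0.650, 0.704, 0.286), e = c(0.072, 0.990, 0.105))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
})

#' Estimate the two stain vectors of an H&E image (Macenko)
#'
#' Projects foreground optical-density pixels onto the plane of their top
#' two principal directions and takes the 1st/99th percentile angles as the
#' extreme stain directions. Foreground pixels are those whose OD vector
#' norm reaches `beta`; weaker pixels count as unstained background.
#' Columns are ordered (hematoxylin, eosin) by the red-channel OD.
#'
#' @param img RGB array in `[0, 1]`.
#' @param beta background OD cutoff (default 0.15).
#' @param alpha percentile (in percent) trimmed from each angular extreme.
#' @return 3 x 2 matrix of unit stain vectors, or NULL when fewer than 20
#'   foreground pixels exist.
#' @export
estimate_stain_matrix <- function(img, beta = 0.15, alpha = 1) {
  od <- matrix(rgb_to_od(img), ncol = 3)
  fg <- od[sqrt(rowSums(od^2)) >= beta, , drop = FALSE]
  if (nrow(fg) < 20) return(NULL)
  # principal plane of the raw (uncentered) OD cloud: stains are
  # directions from the origin, so the second moment is not mean-centered
  ev <- eigen(crossprod(fg) / nrow(fg), symmetric = TRUE)$vectors[, 1:2]
  # orient the plane so projections are mostly positive
  for (k in 1:2) if (sum(fg %*% ev[, k]) < 0) ev[, k] <- -ev[, k]
  proj <- fg %*% ev
  phi <- atan2(proj[, 2], proj[, 1])
  lo <- quantile(phi, alpha / 100, names = FALSE)
  hi <- quantile(phi, 1 - alpha / 100, names = FALSE)
  v1 <- ev %*% c(cos(lo), sin(lo))
  v2 <- ev %*% c(cos(hi), sin(hi))
  stains <- cbind(as.numeric(v1), as.numeric(v2))
  stains[stains < 0] <- 0
  norms <- sqrt(colSums(stains^2))
  if (any(norms == 0)) return(NULL)
  stains <- sweep(stains, 2, norms, "/")
  if (stains[1, 1] < stains[1, 2]) stains <- stains[, 2:1]  # H first
  colnames(stains) <- c("h", "e")
  stains
}

stain_concentrations <- function(od_mat, stains) {
  # least-squares unmixing: od ~ stains %*% conc
  t(qr.solve(stains, t(od_mat)))
}

#' Macenko stain normalization against a reference tile
#'
#' Estimates the stain basis of tile and reference from the singular
#' directions of their foreground optical densities, rescales the tile's
#' stain concentrations so their 99th percentiles match the reference's,
#' and reconstructs the tile in the reference stain basis. Background
#' pixels (OD norm below `beta`) are passed through unchanged. A
#' tile with no foreground at all is returned unchanged with a warning.
#'
#' @param tile,reference RGB arrays in `[0, 1]`.
#' @param beta background OD cutoff (default 0.15).
#' @param alpha angular trim percentile (default 1).
#' @return normalized RGB array, clipped to `[0, 1]`.
#' @export
macenko_normalize <- function(tile, reference, beta = 0.15, alpha = 1) {
  st_t <- estimate_stain_matrix(tile, beta, alpha)
  st_r <- estimate_stain_matrix(reference, beta, alpha)
  if (is.null(st_t) || is.null(st_r)) {
    warning("no foreground pixels for stain estimation; tile passed through")
    return(tile)
  }
  dims <- dim(tile)
  od <- matrix(rgb_to_od(tile), ncol = 3)
  od_ref <- matrix(rgb_to_od(reference), ncol = 3)
  conc <- stain_concentrations(od, st_t)
  conc[conc < 0] <- 0
  conc_ref <- stain_concentrations(od_ref, st_r)
  conc_ref[conc_ref < 0] <- 0
  p99_t <- apply(conc, 2, quantile, 0.99, names = FALSE)
  p99_r <- apply(conc_ref, 2, quantile, 0.99, names = FALSE)
  scale <- ifelse(p99_t > 0, p99_r / p99_t, 1)
  conc <- sweep(conc, 2, scale, "*")
  od_new <- conc %*% t(st_r)
  bg <- sqrt(rowSums(od^2)) < beta
  od_new[bg, ] <- od[bg, ]
  out <- od_to_rgb(array(od_new, dims))
  out
}

#' Hematoxylin concentration channel of an RGB tile
#'
#' Colour-deconvolves the optical densities against the standard H&E stain
#' basis and returns the hematoxylin concentration as a matrix. High values
#' mean strong nuclear stain.
#'
#' @param img RGB array in `[0, 1]`.
#' @return numeric matrix `[h, w]`.
#' @export
hematoxylin_channel <- function(img) {
  od <- matrix(rgb_to_od(img), ncol = 3)
  conc <- stain_concentrations(od, HE_REFERENCE_STAINS)
  m <- matrix(conc[, 1], dim(img)[1], dim(img)[2])
  m[m < 0] <- 0
  m
}

#' Multilevel Otsu thresholds
#'
#' Exhaustive-search generalisation of Otsu's method on a 256-bin
#' histogram: returns the `k - 1` thresholds maximising the between-class
#' variance for `k` classes (k = 2 or 3).
#'
#' @param x numeric values.
#' @param k number of classes (2 or 3).
#' @return numeric vector of `k - 1` thresholds on the scale of `x`.
#' @export
multilevel_otsu <- function(x, k = 2) {
  stopifnot(k %in% c(2, 3))
  r <- range(x, finite = TRUE)
  if (diff(r) == 0) return(rep(r[1], k - 1))
  nb <- 256
  mids <- seq(r[1], r[2], length.out = nb)
  idx <- findInterval(x, mids, all.inside = TRUE)
  p <- tabulate(idx, nb) / length(x)
  w <- cumsum(p)
  m <- cumsum(p * mids)
  mt <- m[nb]
  if (k == 2) {
    # between-class variance for every single threshold
    valid <- w > 0 & w < 1
    sb <- rep(-Inf, nb)
    sb[valid] <- (mt * w[valid] - m[valid])^2 / (w[valid] * (1 - w[valid]))
    return(mids[which.max(sb)])
  }
  cls_stat <- function(i, j) {          # class over bins (i, j]
    wi <- w[j] - if (i == 0) 0 else w[i]
    mi <- m[j] - if (i == 0) 0 else m[i]
    c(wi, mi)
  }
  best <- -Inf
  best_t <- c(1L, 2L)
  for (t1 in 1:(nb - 2)) {
    s1 <- cls_stat(0L, t1)
    if (s1[1] == 0) next
    for (t2 in (t1 + 1):(nb - 1)) {
      s2 <- cls_stat(t1, t2)
      s3 <- cls_stat(t2, nb)
      if (s2[1] == 0 || s3[1] == 0) next
      sb <- s1[2]^2 / s1[1] + s2[2]^2 / s2[1] + s3[2]^2 / s3[1] - mt^2
      if (sb > best) {
        best <- sb
        best_t <- c(t1, t2)
      }
    }
  }
  mids[best_t]
}

#' Segment nuclei in a (normalized) H&E tile
#'
#' Thresholds the hematoxylin channel hierarchically: a 2-class Otsu
#' threshold separates stained tissue from background, then a 3-class
#' multilevel threshold on the same channel isolates the most intensely
#' stained class, which is taken as nuclei. Connected components outside
#' the plausible nucleus area range (default 10-500 square microns) are
#' removed and the survivors relabelled 1..K.
#'
#' @param tile RGB array in `[0, 1]`.
#' @param mpp microns per pixel (default 0.5).
#' @param min_area_um2,max_area_um2 nucleus area filter bounds.
#' @return integer label matrix `[h, w]` (0 = background).
#' @export
segment_nuclei <- function(tile, mpp = 0.5, min_area_um2 = 10,
                           max_area_um2 = 500) {
  hem <- hematoxylin_channel(tile)
  if (stats::var(as.numeric(hem)) < 1e-8) {
    return(matrix(0L, nrow(hem), ncol(hem)))
  }
  hemv <- as.numeric(hem)
  t2 <- multilevel_otsu(hemv, k = 2)
  t3 <- multilevel_otsu(hemv, k = 3)
  # hierarchical rule: the 2-class threshold separates stained nuclei from
  # the rest; the 3-class split refines it. The middle band joins the
  # nuclei only when its mean stain intensity lies on the stained side.
  mid <- hemv[hemv > t3[1] & hemv <= t3[2]]
  cut <- if (length(mid) > 0 && mean(mid) > t2) t3[1] else t3[2]
  mask <- hem > max(t2, cut)
  labels <- EBImage::bwlabel(mask)
  if (max(labels) == 0) return(matrix(0L, nrow(hem), ncol(hem)))
  areas_px <- tabulate(labels[labels > 0], nbins = max(labels))
  areas_um2 <- areas_px * mpp^2
  keep <- which(areas_um2 >= min_area_um2 & areas_um2 <= max_area_um2)
  relabel <- integer(max(labels))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(hem), ncol(hem))
  nz <- labels > 0
  out[nz] <- relabel[labels[nz]]
  out
}

NUCLEUS_FEATURES <- c("area", "circularity", "solidity", "rmean", "gmean",
                      "bmean", "intensity_std", "dist_mean", "dist_max",
                      "dist_min")

#' Per-nucleus morphometry
#'
#' For each labelled nucleus: area (square microns), circularity
#' (`4*pi*A/P^2`), solidity (area over convex-hull area), per-channel mean
#' intensities (0-255 scale), the standard deviation of the grey intensity,
#' and the mean/max/min centroid distance to the other nuclei of the tile
#' (microns; all three are 0 when the tile holds a single nucleus).
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param tile RGB array aligned with `labels`.
#' @param mpp microns per pixel.
#' @return data frame with `tile_id`, `label` and the ten feature columns
#'   of `NUCLEUS_FEATURES`.
#' @export
nucleus_features <- function(labels, tile, mpp = 0.5, tile_id = "tile") {
  K <- max(labels)
  empty <- data.frame(tile_id = character(0), label = integer(0))
  for (f in NUCLEUS_FEATURES) empty[[f]] <- numeric(0)
  if (K == 0) return(empty)
  shp <- EBImage::computeFeatures.shape(labels)
  r <- tile[, , 1]
  g <- tile[, , 2]
  b <- tile[, , 3]
  grey <- (r + g + b) / 3
  cx <- numeric(K)
  cy <- numeric(K)
  rows <- vector("list", K)
  idx_by_label <- split(seq_along(labels), labels[seq_along(labels)])
  idx_by_label[["0"]] <- NULL
  for (k in seq_len(K)) {
    idx <- idx_by_label[[as.character(k)]]
    coords <- arrayInd(idx, dim(labels))
    cx[k] <- mean(coords[, 1])
    cy[k] <- mean(coords[, 2])
    area_px <- length(idx)
    perim_px <- shp[k, "s.perimeter"]
    circ <- if (perim_px > 0) 4 * pi * area_px / perim_px^2 else 0
    hull <- grDevices::chull(coords)
    hull_area <- abs(pracma::polyarea(coords[hull, 1], coords[hull, 2])) +
      length(hull) / 2 + 1
    rows[[k]] <- data.frame(
      tile_id = tile_id, label = k,
      area = area_px * mpp^2,
      circularity = min(circ, 1.2),
      solidity = min(1, area_px / hull_area),
      rmean = mean(r[idx]) * 255,
      gmean = mean(g[idx]) * 255,
      bmean = mean(b[idx]) * 255,
      intensity_std = if (area_px > 1) sd(grey[idx]) * 255 else 0,
      dist_mean = 0, dist_max = 0, dist_min = 0,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (K > 1) {
    D <- as.matrix(dist(cbind(cx, cy))) * mpp
    diag(D) <- NA
    out$dist_mean <- rowMeans(D, na.rm = TRUE)
    out$dist_max <- apply(D, 1, max, na.rm = TRUE)
    out$dist_min <- apply(D, 1, min, na.rm = TRUE)
  }
  out
}

#' Default global histogram ranges for the image-level features
#'
#' Fixed per-feature value ranges used to bin nucleus features into 10-bin
#' histograms. Ranges are global constants (not per-image extremes) so that
#' feature vectors are comparable across foci and patients; values outside
#' a range fall into the closest edge bin.
#'
#' @return named list of `c(lo, hi)` ranges.
#' @export
default_bin_ranges <- function() {
  list(area = c(0, 500), circularity = c(0, 1.2), solidity = c(0, 1),
       rmean = c(0, 255), gmean = c(0, 255), bmean = c(0, 255),
       intensity_std = c(0, 128), dist_mean = c(0, 1500),
       dist_max = c(0, 1500), dist_min = c(0, 1500))
}

hist_stats <- function(x, rng, nbins = 10) {
  xc <- pmin(pmax(x, rng[1]), rng[2])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  idx <- findInterval(xc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins) / length(x)
  s <- sd(x)
  if (length(x) < 2 || is.na(s)) s <- 0
  if (s > 0) {
    m2 <- mean((x - mean(x))^2)
    skew <- mean((x - mean(x))^3) / m2^1.5
    kurt <- mean((x - mean(x))^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  list(bins = p, mean = mean(x), std = s, skewness = skew, kurtosis = kurt,
       entropy = ent)
}

#' Image-level feature vector from pooled nucleus records
#'
#' Dissects each of the ten nucleus features into a density-normalised
#' 10-bin histogram over the fixed global range plus five distribution
#' statistics (mean, standard deviation, Fisher skewness, excess kurtosis,
#' Shannon entropy of the histogram in bits), giving 150 named values.
#' Zero-variance features report skewness and kurtosis as 0 so the vector
#' stays finite.
#'
#' @param records nucleus table from [nucleus_features()] (>= 1 row).
#' @param bin_ranges per-feature ranges (default [default_bin_ranges()]).
#' @return named numeric vector of length 150
#'   (`<feature>_bin1..10`, `<feature>_mean/std/skewness/kurtosis/entropy`).
#' @export
image_level_features <- function(records, bin_ranges = default_bin_ranges()) {
  if (nrow(records) == 0) stop("no nucleus records: empty input")
  out <- numeric(0)
  for (f in NUCLEUS_FEATURES) {
    st <- hist_stats(records[[f]], bin_ranges[[f]])
    v <- c(st$bins, st$mean, st$std, st$skewness, st$kurtosis, st$entropy)
    names(v) <- c(paste0(f, "_bin", 1:10),
                  paste0(f, "_", c("mean", "std", "skewness", "kurtosis",
                                   "entropy")))
    out <- c(out, v)
  }
  out
}

#' Names of the 100 histogram-bin features
#'
#' Convenience selector for the histogram-only subset (10 features x 10
#' bins) of the 150-value image-level vector.
#'
#' @return character vector of 100 names.
#' @export
histogram_feature_names <- function() {
  unlist(lapply(NUCLEUS_FEATURES, function(f) paste0(f, "_bin", 1:10)))
}

#' Per-feature cohort statistics for standardization
#'
#' @param mat matrix of image-level feature vectors (foci in rows).
#' @return list with `center` (means) and `scale` (standard deviations).
#' @export
cohort_feature_stats <- function(mat) {
  list(center = colMeans(mat), scale = apply(mat, 2, sd))
}

#' Correlation between the two foci of one patient
#'
#' Pearson correlation of the two image-level feature vectors. When cohort
#' `center`/`scale` are supplied each feature is standardized against them
#' first (recommended: raw features live on wildly different scales);
#' zero-variance features are dropped. Errors if either standardized
#' vector is constant, since the correlation is then undefined.
#'
#' @param va,vb named feature vectors of equal length.
#' @param center,scale optional cohort statistics ([cohort_feature_stats()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation in `[-1, 1]`.
#' @export
focus_pair_correlation <- function(va, vb, center = NULL, scale = NULL,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(va) == length(vb))
  if (!is.null(center) && !is.null(scale)) {
    keep <- is.finite(scale) & scale > 0
    va <- (va[keep] - center[keep]) / scale[keep]
    vb <- (vb[keep] - center[keep]) / scale[keep]
  }
  if (sd(va) == 0 || sd(vb) == 0) {
    stop("constant feature vector: correlation undefined")
  }
  cor(va, vb, method = method)
}
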