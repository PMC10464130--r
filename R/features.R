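# Texture features: rotation-invariant uniform local binary patterns (LBP,
# P = 8 neighbours at radius 1) computed on the rescaled Radon image, giving a
# 10-bin histogram per patch, plus the 1-D Wasserstein dissimilarity between
# class mean histograms.
#
# The 10 bins are the riu2 labels: circular bit patterns with at most two
# 0<->1 transitions are keyed by their number of set bits (0..8); all other
# patterns share label 9. Exactly 58 of the 256 codes are uniform.

# Neighbour offsets (dr, dc), counterclockwise from the east neighbour with
# rows increasing downward: E, NE, N, NW, W, SW, S, SE.
LBP_OFFSETS <- cbind(
  dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
  dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
)

#' LBP code of a single neighbourhood
#'
#' Bit `i` (i = 0..7) is set when `neighbors[i + 1] >= center`; the code is
#' `sum(bit_i * 2^i)`. Neighbours are ordered counterclockwise starting from
#' the east neighbour. Ties set the bit, so a constant neighbourhood codes to
#' 255.
#'
#' @param center Centre pixel value.
#' @param neighbors Numeric vector of exactly 8 neighbour values.
#' @return Integer code in `[0, 255]`.
#' @export
lbp_code <- function(center, neighbors) {
  if (length(neighbors) != 8L) {
    rs_stop("radonscar_bad_neighbors", "need exactly 8 neighbors, got %d",
            length(neighbors))
  }
  as.integer(sum((neighbors >= center) * 2^(0:7)))
}

# riu2 lookup table for all 256 codes, built once at load time.
riu2_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256L)
      for (code in 0:255) {
        bits <- as.integer(bitwAnd(bitwShiftR(code, 0:7), 1L))
        transitions <- sum(bits != bits[c(2:8, 1)])
        t[code + 1L] <- if (transitions <= 2L) sum(bits) else 9L
      }
      tab <<- t
    }
    tab
  }
})

#' Rotation-invariant uniform label of an LBP code
#'
#' Codes whose circular bit pattern has at most two 0/1 transitions are
#' "uniform" and map to their set-bit count (0..8); every other code maps to
#' 9.
#'
#' @param code Integer LBP code(s) in `[0, 255]`.
#' @return Integer label(s) in `[0, 9]`.
#' @export
riu2_label <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code) | code < 0L | code > 255L)) {
    rs_stop("radonscar_bad_code", "LBP codes must lie in [0, 255]")
  }
  riu2_table()[code + 1L]
}

#' 10-bin riu2 LBP histogram of an image
#'
#' Applies [lbp_code()] at every interior pixel (8 immediate neighbours,
#' radius 1), maps codes through [riu2_label()], and returns the normalized
#' 10-bin label histogram.
#'
#' @param image Numeric matrix, at least 3x3; typically a rescaled Radon
#'   image from [sinogram_to_image()]. Because LBP compares pixel ranks only,
#'   the histogram is invariant to any strictly increasing transform of the
#'   intensities.
#' @return Numeric vector of 10 non-negative frequencies summing to 1, named
#'   `f0`..`f9`.
#' @export
lbp_feature <- function(image) {
  check_image(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 3L || w < 3L) {
    rs_stop("radonscar_image_too_small", "LBP needs at least a 3x3 image")
  }
  centre <- image[2:(h - 1), 2:(w - 1), drop = FALSE]
  codes <- matrix(0L, h - 2L, w - 2L)
  for (i in 1:8) {
    nb <- image[(2:(h - 1)) + LBP_OFFSETS[i, 1],
                (2:(w - 1)) + LBP_OFFSETS[i, 2], drop = FALSE]
    codes <- codes + as.integer(nb >= centre) * 2L^(i - 1L)
  }
  labels <- riu2_label(codes)
  counts <- tabulate(labels + 1L, nbins = 10L)
  stats::setNames(counts / sum(counts), paste0("f", 0:9))
}

#' Feature table for a list of patches
#'
#' Runs each patch through the Radon transform, rescales the sinogram to a
#' grayscale Radon image, and computes its riu2 LBP histogram.
#'
#' @param patches List of [new_patch()] objects.
#' @param angles Projection angles in degrees passed to [radon_transform()].
#' @return Data frame with columns `patch_id`, `label`, `f0`..`f9`.
#' @export
patch_features <- function(patches, angles = 0:179) {
  if (length(patches) == 0L) {
    rs_stop("radonscar_no_patches", "no patches supplied")
  }
  sinos <- radon_transform_batch(patches, angles)
  feats <- t(vapply(sinos, function(s) lbp_feature(sinogram_to_image(s)),
                    numeric(10)))
  df <- data.frame(
    patch_id = sprintf("p%04d", seq_along(patches)),
    label = vapply(patches, `[[`, "", "label")
  )
  cbind(df, as.data.frame(feats))
}

#' Mean feature histogram of one class
#'
#' @param features Feature data frame from [patch_features()] /
#'   [read_feature_table()].
#' @param label Class whose rows are averaged.
#' @return Numeric vector of 10 bin means (sums to 1).
#' @export
class_mean_histogram <- function(features, label) {
  rows <- features[features$label == label, paste0("f", 0:9), drop = FALSE]
  if (nrow(rows) == 0L) {
    rs_stop("radonscar_no_features", "no features with label '%s'", label)
  }
  colMeans(as.matrix(rows))
}

#' 1-D Wasserstein distance between two bin histograms
#'
#' First Wasserstein (earth mover's) distance on the ordered bin index with
#' unit ground distance: `sum_k |CDF_p(k) - CDF_q(k)|`. For 10-bin histograms
#' the maximum, attained between the two extreme one-hot histograms, is 9.
#'
#' @param p,q Non-negative numeric vectors of equal length, each summing to 1
#'   within 1e-6.
#' @return Non-negative distance in bin-index units.
#' @export
wasserstein_1d <- function(p, q) {
  if (length(p) != length(q)) {
    rs_stop("radonscar_bad_histogram", "histograms must have equal length")
  }
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    rs_stop("radonscar_bad_histogram",
            "histograms must be non-negative and sum to 1 (within 1e-6)")
  }
  sum(abs(cumsum(p) - cumsum(q)))
}

#' Class dissimilarity between scar and normal feature histograms
#'
#' Wasserstein distance between the mean scar histogram and the mean normal
#' histogram of a feature table.
#'
#' @inheritParams class_mean_histogram
#' @return A list with `distance` and the two mean histograms.
#' @export
class_dissimilarity <- function(features) {
  hs <- class_mean_histogram(features, "scar")
  hn <- class_mean_histogram(features, "normal")
  list(distance = wasserstein_1d(hs, hn), scar_mean = hs, normal_mean = hn)
}
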