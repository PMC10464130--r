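# Scar-candidate localization on the myocardium: intensity statistics,
# seeded region growing, mean/SD thresholding, mean-intensity binarization,
# and morphological cleanup.

#' Intensity statistics of a masked region
#'
#' Mean and population standard deviation (divisor `n`, not `n - 1`) of the
#' image values under the mask, the two summary statistics every scar
#' threshold in this package is built from.
#'
#' @param image Numeric matrix of HU values.
#' @param mask Logical matrix of the same shape with at least one TRUE pixel.
#' @return A list of class `region_stats` with elements `mean`, `sd` (HU) and
#'   `n_pixels`.
#' @export
region_stats <- function(image, mask) {
  check_image(image); check_mask(mask)
  check_same_shape(image, mask)
  n <- sum(mask)
  if (n == 0L) {
    rs_stop("radonscar_empty_mask", "mask selects no pixels")
  }
  v <- image[mask]
  m <- mean(v)
  structure(
    list(mean = m, sd = sqrt(mean((v - m)^2)), n_pixels = n),
    class = "region_stats"
  )
}

#' @export
#' @method print region_stats
print.region_stats <- function(x, ...) {
  cat(sprintf("region_stats: mean %.2f HU, SD %.2f HU over %d pixels\n",
              x$mean, x$sd, x$n_pixels))
  invisible(x)
}

#' Seeded region growing
#'
#' Breadth-first flood fill from `seed`: the maximal 4-connected component
#' containing the seed in which every pixel differs from the seed value by at
#' most `tolerance` HU. Deterministic; the criterion is fixed relative to the
#' seed value, not a running mean.
#'
#' @param image Numeric matrix of HU values.
#' @param seed `(row, col)` of the seed pixel (1-based).
#' @param tolerance Non-negative HU tolerance; `Inf` floods the whole image.
#' @return A logical mask.
#' @export
region_grow <- function(image, seed, tolerance) {
  check_image(image)
  h <- nrow(image); w <- ncol(image)
  seed <- as.integer(seed)
  if (length(seed) != 2L || seed[1] < 1L || seed[1] > h || seed[2] < 1L || seed[2] > w) {
    rs_stop("radonscar_bad_seed", "seed (%s) is outside the image",
            paste(seed, collapse = ","))
  }
  if (!is.numeric(tolerance) || length(tolerance) != 1L || is.na(tolerance) || tolerance < 0) {
    rs_stop("radonscar_bad_tolerance", "tolerance must be a non-negative number")
  }
  admissible <- abs(image - image[seed[1], seed[2]]) <= tolerance
  grown <- matrix(FALSE, h, w)
  grown[seed[1], seed[2]] <- TRUE
  repeat {
    frontier <- dilate(grown, se_cross3()) & admissible & !grown
    if (!any(frontier)) break
    grown <- grown | frontier
  }
  grown
}

#' Threshold scar candidates at mean + k SD of healthy tissue
#'
#' A myocardial pixel is a scar candidate when its HU value strictly exceeds
#' `healthy$mean + k * healthy$sd`. The conventional literature rule uses
#' `k = 3`; `k = 2` gives the more permissive patch-stage contrast rule (see
#' [contrast_rule()]).
#'
#' @param image Numeric matrix of HU values.
#' @param myocardium Logical myocardium mask.
#' @param healthy A [region_stats()] for healthy myocardium (or any list with
#'   `mean` and `sd`).
#' @param k SD multiplier, default 3.
#' @return Logical mask, a subset of `myocardium`.
#' @export
scar_threshold <- function(image, myocardium, healthy, k = 3) {
  check_image(image); check_mask(myocardium, "myocardium")
  check_same_shape(image, myocardium)
  if (is.null(healthy$mean) || is.null(healthy$sd) || healthy$sd < 0) {
    rs_stop("radonscar_bad_stats", "healthy must supply mean and sd >= 0")
  }
  myocardium & (image > healthy$mean + k * healthy$sd)
}

#' Patch-stage contrast rule (mean + 2 SD)
#'
#' Marks the high-contrast pixels used when assembling patches: value strictly
#' above `stats$mean + 2 * stats$sd`. Equivalent to
#' `scar_threshold(..., k = 2)`.
#'
#' @inheritParams scar_threshold
#' @param stats A [region_stats()].
#' @export
contrast_rule <- function(image, myocardium, stats) {
  scar_threshold(image, myocardium, stats, k = 2)
}

#' Binarize a region at its mean intensity
#'
#' TRUE exactly where the mask is TRUE and the value strictly exceeds the mean
#' over the mask; the TRUE ("white") pixels are the higher-intensity, higher-
#' contrast areas.
#'
#' @inheritParams region_stats
#' @export
binarize_mean <- function(image, mask) {
  s <- region_stats(image, mask)
  mask & (image > s$mean)
}

#' Estimate healthy-myocardium statistics in the presence of scar
#'
#' Statistics taken over the whole myocardium are contaminated by the
#' hyperintense scar, inflating both mean and SD until `mean + k*SD` can
#' exceed the scar intensity itself. This estimator first binarizes the
#' myocardium at its mean intensity ([binarize_mean()]) — the "white",
#' above-mean spots are the high-contrast candidates — and then computes
#' [region_stats()] over the remaining below-mean ("black") pixels, which are
#' dominated by healthy tissue.
#'
#' @inheritParams region_stats
#' @param mask Logical myocardium mask.
#' @return A [region_stats()] for the healthy reference region.
#' @export
estimate_healthy_stats <- function(image, mask) {
  white <- binarize_mean(image, mask)
  healthy_px <- mask & !white
  if (!any(healthy_px)) {
    rs_stop("radonscar_empty_mask", "no below-mean pixels to estimate healthy tissue")
  }
  region_stats(image, healthy_px)
}

#' Full scar-candidate localization pipeline
#'
#' Thresholds the myocardium at `mean + k * SD` of the supplied healthy
#' statistics, then cleans the candidate mask morphologically. The default
#' order `"open-close"` removes speckle first (opening) and then fills
#' pinholes (closing).
#'
#' @inheritParams scar_threshold
#' @param se Structuring element for the cleanup, default 3x3 square.
#' @param order `"open-close"` or `"close-open"`.
#' @return The final scar-candidate mask.
#' @export
scar_pipeline <- function(image, myocardium, healthy, k = 3,
                          se = se_square3(), order = c("open-close", "close-open")) {
  order <- match.arg(order)
  cand <- scar_threshold(image, myocardium, healthy, k = k)
  if (order == "open-close") {
    closing(opening(cand, se), se)
  } else {
    opening(closing(cand, se), se)
  }
}
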