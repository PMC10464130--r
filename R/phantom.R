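# Synthetic short-axis cardiac-CT-like phantom with ground-truth masks.
#
# The phantom emulates the intensity regime of delayed-enhancement cardiac CT:
# an annular left-ventricular myocardium at ~59 +/- 21 HU, with hyperintense
# scar arcs whose mean clears the mean + 3 SD detection rule and whose noise
# field is spatially smoothed, giving scar a texture as well as an intensity
# contrast. Background (blood pool and exterior) is constant 0 HU: every
# statistic in the pipeline is computed inside the myocardium mask, so
# background realism is irrelevant.

#' Phantom specification
#'
#' @param image_size Side length in pixels (square image).
#' @param center `(row, col)` of the annulus centre; default image centre.
#' @param inner_radius,outer_radius Radii (pixels) bounding the myocardial
#'   annulus; must satisfy `0 < inner < outer < image_size / 2`.
#' @param myo_mean,myo_sd Healthy myocardium intensity, HU.
#' @param scar_arcs List of `c(start, end)` polar-angle intervals in degrees
#'   (counterclockwise from the positive column axis, in `[0, 360)`; an
#'   interval with `start > end` wraps through 0). Pixels of the annulus whose
#'   angle falls in any arc are scar.
#' @param scar_mean,scar_sd Scar intensity, HU; `scar_mean` must exceed
#'   `myo_mean + 3 * myo_sd` so the detection rule can fire.
#' @param scar_texture_scale Width (pixels) of the square moving-average
#'   kernel applied to the scar noise field; values below 2 disable smoothing.
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256,
                         center = c((image_size + 1) / 2, (image_size + 1) / 2),
                         inner_radius = 55,
                         outer_radius = 105,
                         myo_mean = 59,
                         myo_sd = 21,
                         scar_arcs = list(c(20, 90), c(200, 270)),
                         scar_mean = myo_mean + 4 * myo_sd,
                         scar_sd = 21,
                         scar_texture_scale = 3,
                         seed = 1L) {
  spec <- list(
    image_size = as.integer(image_size), center = as.numeric(center),
    inner_radius = inner_radius, outer_radius = outer_radius,
    myo_mean = myo_mean, myo_sd = myo_sd,
    scar_arcs = scar_arcs, scar_mean = scar_mean, scar_sd = scar_sd,
    scar_texture_scale = scar_texture_scale, seed = as.integer(seed)
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$image_size < 8) {
    rs_stop("radonscar_bad_phantom_spec", "image_size too small")
  }
  if (!(spec$inner_radius > 0 && spec$inner_radius < spec$outer_radius &&
        spec$outer_radius < spec$image_size / 2)) {
    rs_stop("radonscar_bad_phantom_spec",
            "need 0 < inner_radius < outer_radius < image_size/2")
  }
  if (spec$myo_sd < 0 || spec$scar_sd < 0 || spec$scar_texture_scale < 0) {
    rs_stop("radonscar_bad_phantom_spec", "sd and texture scale must be >= 0")
  }
  if (!(spec$scar_mean > spec$myo_mean + 3 * spec$myo_sd)) {
    rs_stop("radonscar_bad_phantom_spec",
            "scar_mean must exceed myo_mean + 3*myo_sd")
  }
  for (a in spec$scar_arcs) {
    if (length(a) != 2L || anyNA(a)) {
      rs_stop("radonscar_bad_phantom_spec", "each scar arc must be c(start, end)")
    }
  }
  invisible(spec)
}

# 2-D box moving average with zero padding, kernel width rounded to odd.
smooth_box <- function(m, width) {
  w <- max(1L, as.integer(round(width)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(m)
  r <- (w - 1L) %/% 2L
  h <- nrow(m); wd <- ncol(m)
  pad <- matrix(0, h + 2L * r, wd + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + wd)] <- m
  # separable box sums via sliding-window column sums on each axis
  rows <- running_colsum(pad, w)
  out <- t(running_colsum(t(rows), w))
  out / (w * w)
}

# Polar angle of each pixel: degrees CCW from the +column axis, rows downward.
phantom_geometry <- function(spec) {
  n <- spec$image_size
  rr <- matrix(seq_len(n), n, n) - spec$center[1]
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - spec$center[2]
  radius <- sqrt(rr^2 + cc^2)
  angle <- (atan2(-rr, cc) * 180 / pi) %% 360
  myocardium <- radius >= spec$inner_radius & radius <= spec$outer_radius
  in_arc <- matrix(FALSE, n, n)
  for (a in spec$scar_arcs) {
    s <- a[1] %% 360; e <- a[2] %% 360
    hit <- if (s <= e) angle >= s & angle <= e else angle >= s | angle <= e
    in_arc <- in_arc | hit
  }
  list(myocardium = myocardium, scar = myocardium & in_arc)
}

#' Generate a synthetic short-axis phantom
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (numeric HU matrix), `myocardium` and `scar`
#'   (logical masks, `scar` a subset of `myocardium`), and the `spec`.
#' @details Healthy myocardium pixels are i.i.d. `Normal(myo_mean, myo_sd)`;
#'   scar pixels are `scar_mean` plus a `Normal(0, scar_sd)` field smoothed by
#'   a `scar_texture_scale`-wide box kernel, so scar differs from healthy
#'   tissue in texture as well as intensity. Deterministic given `spec$seed`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  geom <- phantom_geometry(spec)
  n <- spec$image_size
  img <- matrix(0, n, n)
  normal_px <- geom$myocardium & !geom$scar
  with_seed(spec$seed, {
    img[normal_px] <- rnorm(sum(normal_px), spec$myo_mean, spec$myo_sd)
    noise <- matrix(rnorm(n * n, 0, spec$scar_sd), n, n)
    smoothed <- smooth_box(noise, spec$scar_texture_scale)
    img[geom$scar] <- spec$scar_mean + smoothed[geom$scar]
  })
  list(image = img, myocardium = geom$myocardium, scar = geom$scar, spec = spec)
}

#' Sample balanced labeled patch sets from a phantom
#'
#' Draws `n_per_class` patches lying entirely inside the ground-truth scar
#' mask and `n_per_class` entirely inside healthy myocardium (myocardium minus
#' scar), by a seeded shuffle of the eligible origins of each class.
#'
#' @param spec A [phantom_spec()].
#' @param n_per_class Number of patches per class.
#' @param patch_size Tile side length, default 25.
#' @param overlap_policy `"any"` or `"disjoint"` (see [extract_patches()]).
#' @return A list with `patches` (list of patch objects, scar first) and the
#'   generated `phantom`.
#' @export
phantom_patch_sets <- function(spec = phantom_spec(), n_per_class,
                               patch_size = 25, overlap_policy = "any") {
  ph <- generate_phantom(spec)
  normal_mask <- ph$myocardium & !ph$scar
  scar <- extract_patches(ph$image, ph$scar, label = "scar",
                          n = n_per_class, patch_size = patch_size,
                          seed = ph$spec$seed + 1L, overlap_policy = overlap_policy,
                          source_id = "phantom")
  normal <- extract_patches(ph$image, normal_mask, label = "normal",
                            n = n_per_class, patch_size = patch_size,
                            seed = ph$spec$seed + 2L, overlap_policy = overlap_policy,
                            source_id = "phantom")
  list(patches = c(scar, normal), phantom = ph)
}
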