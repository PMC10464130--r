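# Radon transform of square tiles: line-integral projections over a set of
# angles, producing the sinogram ("Radon image") the texture descriptor is
# built from.
#
# Definition implemented: for angle theta the tile is conceptually rotated by
# -theta about its centre (bilinear splatting, zero padding outside) and the
# columns are summed; the column index, measured from the centre, is the
# signed offset. Because the row-direction splat weights of each pixel sum to
# one, this collapses exactly to a per-pixel accumulation: every pixel's
# value is distributed between the two offset bins adjacent to its rotated
# column coordinate with linear weights. Mass is therefore conserved exactly
# per angle. The tile is zero-padded to beyond its diagonal so no mass leaves
# the offset range under any rotation, and the whole map is precomputed as
# one sparse operator per (size, angles) pair and cached; applying it is a
# single sparse matrix product.

# Padded side length: odd, and wide enough that both offset bins adjacent to
# any tile pixel's rotated coordinate exist at every angle.
radon_pad_size <- function(n) {
  p <- as.integer(ceiling(n * sqrt(2))) + 4L
  if (p %% 2L == 0L) p <- p + 1L
  p
}

projector_cache <- new.env(parent = emptyenv())

# Sparse operator mapping a vectorized p x p padded tile (column-major) to
# the stacked sinogram (offsets fastest, angles slowest).
radon_projector <- function(p, angles) {
  key <- paste0(p, "|", paste(signif(angles, 12), collapse = ","))
  hit <- projector_cache[[key]]
  if (!is.null(hit)) return(hit)

  ctr <- (p + 1) / 2
  px <- expand.grid(r = seq_len(p), o = seq_len(p))  # source pixels, col-major
  dr <- px$r - ctr; dc <- px$o - ctr
  src_idx <- seq_len(p * p)
  n_angles <- length(angles)
  ti <- vector("list", n_angles); tj <- vector("list", n_angles)
  tx <- vector("list", n_angles)
  for (a in seq_len(n_angles)) {
    th <- angles[a] * pi / 180
    # rotated column coordinate of each source pixel (rows increase downward)
    t_off <- ctr - dr * sin(th) + dc * cos(th)
    b0 <- floor(t_off); frac <- t_off - b0
    bin <- c(b0, b0 + 1)
    wgt <- c(1 - frac, frac)
    src <- c(src_idx, src_idx)
    ok <- bin >= 1 & bin <= p & wgt > 0
    ti[[a]] <- bin[ok] + (a - 1L) * p
    tj[[a]] <- src[ok]
    tx[[a]] <- wgt[ok]
  }
  op <- Matrix::sparseMatrix(
    i = unlist(ti), j = unlist(tj), x = unlist(tx),
    dims = c(p * n_angles, p * p)
  )
  projector_cache[[key]] <- op
  op
}

pad_tile <- function(m, p) {
  n <- nrow(m)
  off <- (p - n) %/% 2L
  out <- matrix(0, p, p)
  out[(off + 1L):(off + n), (off + 1L):(off + n)] <- m
  out
}

#' Radon transform of a square tile
#'
#' Computes line-integral projections of the tile for each angle, one
#' projection sample per unit offset from the tile centre.
#'
#' @param patch A [new_patch()] object or a square numeric matrix.
#' @param angles Projection angles in degrees; default `0:179` (the
#'   conventional half-circle at 1 degree steps). At 0 degrees the projection
#'   equals the padded tile's column sums.
#' @return A list of class `sinogram` with `values` (matrix, rows = offsets,
#'   columns = angles), `angles`, and `offsets` (signed pixel distances from
#'   the centre, symmetric about 0 at unit spacing).
#' @export
radon_transform <- function(patch, angles = 0:179) {
  m <- if (inherits(patch, "patch")) patch$pixels else patch
  check_image(m, "patch")
  if (nrow(m) != ncol(m)) {
    rs_stop("radonscar_nonsquare", "Radon input must be square, got %dx%d",
            nrow(m), ncol(m))
  }
  if (length(angles) == 0L) {
    rs_stop("radonscar_no_angles", "angles must be nonempty")
  }
  p <- radon_pad_size(nrow(m))
  op <- radon_projector(p, angles)
  values <- matrix(as.numeric(op %*% as.vector(pad_tile(m, p))), nrow = p)
  new_sinogram(values, angles, p)
}

new_sinogram <- function(values, angles, p) {
  structure(
    list(values = values, angles = as.numeric(angles),
         offsets = seq_len(p) - (p + 1) / 2),
    class = "sinogram"
  )
}

# Batched transform: one sparse product for a list of same-sized tiles.
# Returns a list of sinograms aligned with `patches`.
radon_transform_batch <- function(patches, angles = 0:179) {
  if (length(patches) == 0L) return(list())
  mats <- lapply(patches, function(pt) if (inherits(pt, "patch")) pt$pixels else pt)
  n <- nrow(mats[[1]])
  for (m in mats) {
    if (nrow(m) != n || ncol(m) != n) {
      rs_stop("radonscar_nonsquare", "all tiles in a batch must be %dx%d", n, n)
    }
  }
  p <- radon_pad_size(n)
  op <- radon_projector(p, angles)
  stacked <- vapply(mats, function(m) as.vector(pad_tile(m, p)), numeric(p * p))
  out <- as.matrix(op %*% stacked)
  lapply(seq_along(mats), function(i) {
    new_sinogram(matrix(out[, i], nrow = p), angles, p)
  })
}

#' Render a sinogram as a grayscale image
#'
#' Linearly rescales the sinogram values to `[0, 255]` (minimum to 0, maximum
#' to 255); a constant sinogram maps to all zeros. This rescaled "Radon
#' image" is the input to the LBP texture operator.
#'
#' @param s A `sinogram`.
#' @return A numeric matrix in `[0, 255]` with the sinogram's shape.
#' @export
sinogram_to_image <- function(s) {
  v <- s$values
  rng <- range(v)
  if (rng[1] == rng[2]) return(matrix(0, nrow(v), ncol(v)))
  (v - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Write a sinogram as csv-matrix plus JSON sidecar
#'
#' @param s A `sinogram`.
#' @param path_base Path without extension; writes `<base>.csv` and
#'   `<base>.json` (angles and offsets).
#' @export
write_sinogram <- function(s, path_base) {
  write_csv_matrix(s$values, paste0(path_base, ".csv"))
  jsonlite::write_json(list(angles = s$angles, offsets = s$offsets),
                       paste0(path_base, ".json"), digits = NA)
  invisible(path_base)
}
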