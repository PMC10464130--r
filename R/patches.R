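# Extraction of fixed-size labeled tiles from class masks.

#' Create a patch object
#'
#' @param pixels Square numeric matrix of HU values.
#' @param label `"scar"` or `"normal"`.
#' @param origin `(row, col)` of the tile's top-left corner in the source
#'   image (1-based).
#' @param source_id Identifier of the source image.
#' @return A list of class `patch`.
#' @export
new_patch <- function(pixels, label, origin, source_id = "") {
  check_image(pixels, "pixels")
  if (nrow(pixels) != ncol(pixels)) {
    rs_stop("radonscar_bad_patch", "patch pixels must be square")
  }
  if (!label %in% c("scar", "normal")) {
    rs_stop("radonscar_bad_patch", "label must be 'scar' or 'normal'")
  }
  structure(
    list(pixels = pixels, label = label,
         origin = as.integer(origin), source_id = as.character(source_id)),
    class = "patch"
  )
}

#' Top-left corners of tiles fully inside a mask
#'
#' Returns every `(row, col)` origin whose `patch_size` x `patch_size` tile
#' lies entirely on TRUE mask pixels, in row-major order.
#'
#' @param mask Logical matrix.
#' @param patch_size Tile side length.
#' @return A two-column integer matrix of origins (possibly zero rows).
#' @export
eligible_origins <- function(mask, patch_size = 25) {
  check_mask(mask)
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) {
    rs_stop("radonscar_bad_patch_size", "patch_size must be >= 1")
  }
  if (patch_size > nrow(mask) || patch_size > ncol(mask)) {
    rs_stop("radonscar_bad_patch_size",
            "patch_size %d exceeds the %dx%d mask", patch_size, nrow(mask), ncol(mask))
  }
  # an origin is eligible iff the erosion of the mask by the full tile
  # footprint (anchored at the top-left corner) is TRUE there
  ok <- matrix(TRUE, nrow(mask) - patch_size + 1L, ncol(mask) - patch_size + 1L)
  for (dc in 0:(patch_size - 1L)) {
    colblock <- mask[, (1L + dc):(ncol(mask) - patch_size + 1L + dc), drop = FALSE]
    ok <- ok & (running_colsum(colblock, patch_size) == patch_size)
  }
  idx <- which(ok, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("row", "col")
  idx
}

#' Extract labeled patches from a masked region
#'
#' Samples `n` origins by a seeded shuffle of [eligible_origins()] and cuts
#' the corresponding tiles. Under `overlap_policy = "disjoint"` the shuffled
#' list is scanned greedily, skipping any origin whose tile overlaps an
#' already accepted one.
#'
#' @param image Numeric matrix of HU values.
#' @param mask Logical matrix marking the class region.
#' @param label Class label for every returned patch.
#' @param n Number of patches to return.
#' @param patch_size Tile side length, default 25.
#' @param seed Integer seed for the shuffle.
#' @param overlap_policy `"any"` (tiles may overlap) or `"disjoint"`.
#' @param source_id Identifier recorded on each patch.
#' @return A list of [new_patch()] objects with unique origins.
#' @export
extract_patches <- function(image, mask, label, n, patch_size = 25, seed = 1L,
                            overlap_policy = c("any", "disjoint"),
                            source_id = "") {
  check_image(image); check_mask(mask)
  check_same_shape(image, mask)
  overlap_policy <- match.arg(overlap_policy)
  n <- as.integer(n)
  if (n == 0L) return(list())
  origins <- eligible_origins(mask, patch_size)
  avail <- nrow(origins)
  if (avail == 0L) {
    rs_stop("radonscar_insufficient_origins",
            "need %d origins but only 0 are eligible", n)
  }
  perm <- with_seed(seed, sample.int(avail))
  origins <- origins[perm, , drop = FALSE]
  chosen <- matrix(0L, 0L, 2L)
  for (i in seq_len(avail)) {
    o <- origins[i, ]
    if (overlap_policy == "disjoint" && nrow(chosen) > 0L) {
      overlaps <- abs(chosen[, 1] - o[1]) < patch_size &
                  abs(chosen[, 2] - o[2]) < patch_size
      if (any(overlaps)) next
    }
    chosen <- rbind(chosen, o)
    if (nrow(chosen) == n) break
  }
  if (nrow(chosen) < n) {
    rs_stop("radonscar_insufficient_origins",
            "need %d origins but only %d are available under policy '%s'",
            n, nrow(chosen), overlap_policy)
  }
  lapply(seq_len(n), function(i) {
    r <- chosen[i, 1]; c <- chosen[i, 2]
    new_patch(image[r:(r + patch_size - 1L), c:(c + patch_size - 1L)],
              label = label, origin = c(r, c), source_id = source_id)
  })
}

#' Serialize / load a patch set
#'
#' Writes each patch as a csv-matrix tile `patch_<id>.csv` plus a manifest
#' `manifest.csv` with columns `patch_id,label,row,col,source_id`.
#'
#' @param patches List of patch objects.
#' @param dir Output directory (created if needed).
#' @return `write_patches()` the manifest path; `read_patches()` the patch
#'   list.
#' @export
write_patches <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("p%04d", seq_along(patches))
  for (i in seq_along(patches)) {
    write_csv_matrix(patches[[i]]$pixels, file.path(dir, paste0("patch_", ids[i], ".csv")))
  }
  manifest <- data.frame(
    patch_id = ids,
    label = vapply(patches, `[[`, "", "label"),
    row = vapply(patches, function(p) p$origin[1], 0L),
    col = vapply(patches, function(p) p$origin[2], 0L),
    source_id = vapply(patches, `[[`, "", "source_id")
  )
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patches
#' @export
read_patches <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    px <- read_csv_matrix(file.path(dir, paste0("patch_", manifest$patch_id[i], ".csv")))
    new_patch(px, manifest$label[i], c(manifest$row[i], manifest$col[i]),
              manifest$source_id[i])
  })
}
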