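# Image, mask, feature-table and metrics I/O with fixed dialects.
#
# HU images travel in three dialects:
#   * csv     - comma-separated rows, no header, values are HU verbatim
#   * png16   - 16-bit grayscale PNG; stored integer = HU + 1024
#   * tiff    - 16-bit grayscale TIFF; stored integer = HU + 1024
# The +1024 offset is the CT convention that lets unsigned integer formats
# carry negative HU (air = -1024 maps to 0).
# Masks are 8-bit PNG (0/255) or csv (0/1).

HU_OFFSET <- 1024

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = "png16",
    tif = , tiff = "tiff",
    csv = , txt = "csv",
    rs_stop("radonscar_unknown_dialect", "cannot infer dialect from '%s'", path)
  )
}

read_csv_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, ",", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    rs_stop("radonscar_ragged_csv", "ragged rows in csv-matrix '%s'", path)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    rs_stop("radonscar_bad_csv_value", "non-numeric value in csv-matrix '%s'", path)
  }
  matrix(vals, nrow = length(rows), ncol = widths[1], byrow = TRUE)
}

write_csv_matrix <- function(m, path) {
  writeLines(apply(m, 1L, paste, collapse = ","), path)
}

png_bit_depth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 26L)
  as.integer(hdr[25L])  # IHDR bit-depth byte
}

#' Read an image of Hounsfield units
#'
#' @param path File path.
#' @param dialect One of `"auto"`, `"png16"`, `"tiff"`, `"csv"`. `"auto"`
#'   infers from the file extension.
#' @return A numeric matrix of HU values.
#' @details For the integer dialects (`png16`, `tiff`) stored values are mapped
#'   to HU by subtracting 1024; csv carries HU verbatim. Only 16-bit grayscale
#'   PNG/TIFF are accepted.
#' @export
read_hu_image <- function(path, dialect = c("auto", "png16", "tiff", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rs_stop("radonscar_missing_file", "no such file: '%s'", path)
  }
  if (dialect == "auto") dialect <- guess_dialect(path)
  if (dialect == "csv") return(read_csv_matrix(path))
  if (dialect == "png16") {
    if (png_bit_depth(path) != 16L) {
      rs_stop("radonscar_bad_bit_depth", "'%s' is not a 16-bit PNG", path)
    }
    m <- png::readPNG(path)
    if (length(dim(m)) != 2L) {
      rs_stop("radonscar_bad_bit_depth", "'%s' is not single-channel grayscale", path)
    }
    return(round(m * 65535) - HU_OFFSET)
  }
  # tiff
  info <- tiff::readTIFF(path, payload = FALSE)
  if (info$bits.per.sample[1] != 16L) {
    rs_stop("radonscar_bad_bit_depth", "'%s' is not a 16-bit TIFF", path)
  }
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L) {
    rs_stop("radonscar_bad_bit_depth", "'%s' is not single-channel grayscale", path)
  }
  m - HU_OFFSET
}

#' Write an image of Hounsfield units
#'
#' @inheritParams read_hu_image
#' @param image Numeric matrix of HU values. For the integer dialects every
#'   `HU + 1024` must fit in `[0, 65535]` and be a whole number.
#' @return The path, invisibly.
#' @export
write_hu_image <- function(image, path, dialect = c("auto", "png16", "tiff", "csv")) {
  check_image(image)
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- guess_dialect(path)
  if (dialect == "csv") {
    write_csv_matrix(image, path)
    return(invisible(path))
  }
  stored <- image + HU_OFFSET
  if (any(stored < 0 | stored > 65535) || any(stored != round(stored))) {
    rs_stop("radonscar_unencodable_hu",
            "HU values must be integers in [-1024, 64511] for dialect '%s'", dialect)
  }
  if (dialect == "png16") {
    write_png16(stored, path)
  } else {
    tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a binary mask
#'
#' Accepts 0/255 grayscale PNG or 0/1 csv-matrix; any other stored value is an
#' error.
#'
#' @inheritParams read_hu_image
#' @return A logical matrix.
#' @export
read_mask <- function(path, dialect = c("auto", "png", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    rs_stop("radonscar_missing_file", "no such file: '%s'", path)
  }
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "png") "png" else "csv"
  }
  if (dialect == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) != 2L) {
      rs_stop("radonscar_bad_mask_value", "'%s' is not single-channel grayscale", path)
    }
    stored <- round(m * 255)
    if (!all(stored %in% c(0, 255))) {
      rs_stop("radonscar_bad_mask_value", "mask PNG '%s' has values other than 0/255", path)
    }
    return(stored == 255)
  }
  m <- read_csv_matrix(path)
  if (!all(m %in% c(0, 1))) {
    rs_stop("radonscar_bad_mask_value", "mask csv '%s' has values other than 0/1", path)
  }
  m == 1
}

#' Write a binary mask
#'
#' @param mask Logical matrix.
#' @inheritParams read_hu_image
#' @export
write_mask <- function(mask, path, dialect = c("auto", "png", "csv")) {
  check_mask(mask)
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "png") "png" else "csv"
  }
  if (dialect == "png") {
    png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  } else {
    write_csv_matrix(matrix(as.integer(mask), nrow(mask)), path)
  }
  invisible(path)
}

#' Write / read a feature table
#'
#' CSV with header `patch_id,label,f0..f9`; one row per patch.
#'
#' @param features Data frame with columns `patch_id`, `label`, `f0`..`f9`.
#' @param path File path.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features))
  need <- c("patch_id", "label", paste0("f", 0:9))
  if (!all(need %in% names(features))) {
    rs_stop("radonscar_bad_feature_table", "feature table must have columns %s",
            paste(need, collapse = ","))
  }
  write.csv(features[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) {
    rs_stop("radonscar_missing_file", "no such file: '%s'", path)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patch_id", "label", paste0("f", 0:9))
  if (!all(need %in% names(df))) {
    rs_stop("radonscar_bad_feature_table", "'%s' is not a feature table", path)
  }
  df
}

#' Write a metrics list as JSON
#'
#' @param metrics A named list of scalars / lists.
#' @param path Output path.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- minimal 16-bit grayscale PNG encoder -----------------------------------
# png::writePNG only emits 8-bit samples; 16-bit output is encoded here
# directly (signature, IHDR, one zlib-compressed IDAT of filter-0 scanlines,
# IEND). memCompress() already yields the RFC 1950 zlib stream IDAT requires.

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256L)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1L))  # 0xEDB88320
          } else {
            bitwShiftR(bitwAnd(c, -2L), 1L)
          }
        }
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(tab[idx + 1L], bitwShiftR(bitwAnd(c, -256L), 8L))
  }
  bitwXor(c, -1L)
}

u32_bytes <- function(x) {
  # big-endian bytes of a 32-bit value given as (possibly negative) R integer
  xu <- if (x < 0) x + 4294967296 else as.numeric(x)
  as.raw(c(xu %/% 16777216, (xu %/% 65536) %% 256, (xu %/% 256) %% 256, xu %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_bytes(length(data)), body, u32_bytes(crc32(body)))
}

write_png16 <- function(stored, path) {
  h <- nrow(stored); w <- ncol(stored)
  v <- as.integer(t(stored))                 # row-major pixel order
  bytes <- integer(2L * length(v))           # big-endian 16-bit samples
  bytes[c(TRUE, FALSE)] <- v %/% 256L
  bytes[c(FALSE, TRUE)] <- v %% 256L
  scan <- matrix(bytes, nrow = 2L * w)       # one column per scanline
  idat_raw <- as.raw(as.vector(rbind(0L, scan)))  # filter byte 0 per scanline
  ihdr <- c(u32_bytes(w), u32_bytes(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(
    as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", memCompress(idat_raw, "gzip")),
    png_chunk("IEND", raw(0))
  )
  writeBin(out, path)
  invisible(path)
}
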