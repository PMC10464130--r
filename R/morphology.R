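# Binary mathematical morphology on logical matrices.
#
# A structuring element (SE) is a set of integer (dr, dc) offsets containing
# (0, 0). Pixels outside the image are treated as FALSE, so erosion shrinks
# objects at the borders; the complement-duality with dilation therefore holds
# exactly only away from the image boundary.

#' Structuring elements
#'
#' A structuring element is a two-column integer matrix of `(dr, dc)` offsets
#' that must include `(0, 0)`. `se_cross3()` is the 4-neighbourhood plus
#' centre; `se_square3()` the full 3x3 square.
#'
#' @param offsets Two-column matrix (or list coercible to one) of integer
#'   offsets.
#' @return An object of class `structuring_element`.
#' @export
structuring_element <- function(offsets) {
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 2L || nrow(offsets) < 1L ||
      any(offsets != round(offsets))) {
    rs_stop("radonscar_bad_se", "offsets must be a non-empty two-column integer matrix")
  }
  storage.mode(offsets) <- "integer"
  if (!any(offsets[, 1] == 0L & offsets[, 2] == 0L)) {
    rs_stop("radonscar_bad_se", "structuring element must contain (0,0)")
  }
  offsets <- unique(offsets)
  dimnames(offsets) <- list(NULL, c("dr", "dc"))
  structure(offsets, class = c("structuring_element", "matrix"))
}

#' @rdname structuring_element
#' @export
se_cross3 <- function() {
  structuring_element(rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
}

#' @rdname structuring_element
#' @export
se_square3 <- function() {
  structuring_element(as.matrix(expand.grid(dr = -1:1, dc = -1:1)))
}

#' @rdname structuring_element
#' @param se A structuring element.
#' @export
se_reflect <- function(se) {
  structuring_element(-unclass(se))
}

# Shift a mask by (dr, dc), padding with `fill`.
shift_mask <- function(mask, dr, dc, fill = FALSE) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(fill, h, w)
  r_lo <- max(1L, 1L + dr); r_hi <- min(h, h + dr)
  c_lo <- max(1L, 1L + dc); c_hi <- min(w, w + dc)
  if (r_lo > r_hi || c_lo > c_hi) return(out)
  r_src <- r_lo:r_hi; c_src <- c_lo:c_hi
  out[r_src - dr, c_src - dc] <- mask[r_src, c_src]
  out
}

morph_check <- function(mask, se) {
  check_mask(mask)
  if (!inherits(se, "structuring_element")) se <- structuring_element(se)
  se
}

#' Binary morphological operators
#'
#' `erode()` keeps a pixel when every SE offset lands on a TRUE pixel;
#' `dilate()` when any does. Out-of-image positions count as FALSE for both.
#' `opening()` is erosion followed by dilation, `closing()` the reverse.
#'
#' @param mask Logical matrix.
#' @param se A [structuring_element()]; default 3x3 square.
#' @return A logical matrix of the same shape.
#' @export
erode <- function(mask, se = se_square3()) {
  se <- morph_check(mask, se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se))) {
    out <- out & shift_mask(mask, se[i, 1], se[i, 2], fill = FALSE)
  }
  out
}

#' @rdname erode
#' @export
dilate <- function(mask, se = se_square3()) {
  se <- morph_check(mask, se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(se))) {
    out <- out | shift_mask(mask, se[i, 1], se[i, 2], fill = FALSE)
  }
  out
}

#' @rdname erode
#' @export
opening <- function(mask, se = se_square3()) {
  dilate(erode(mask, se), se)
}

#' @rdname erode
#' @export
closing <- function(mask, se = se_square3()) {
  erode(dilate(mask, se), se)
}
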