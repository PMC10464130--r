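# Internal helpers shared across modules.

# Raise a classed error so callers can distinguish failure modes.
rs_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "radonscar_error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Sliding-window sums of width `w` down each column; output has
# nrow(m) - w + 1 rows.
running_colsum <- function(m, w) {
  cs <- apply(m, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = nrow(m))
  top <- cs[w, , drop = FALSE]
  if (nrow(cs) == w) return(top)
  rbind(top, cs[(w + 1L):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE])
}

check_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    rs_stop("radonscar_bad_image", "`%s` must be a numeric matrix", arg)
  }
  if (any(!is.finite(image))) {
    rs_stop("radonscar_bad_image", "`%s` contains non-finite values", arg)
  }
  invisible(image)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    rs_stop("radonscar_bad_mask", "`%s` must be a logical matrix", arg)
  }
  if (anyNA(mask)) {
    rs_stop("radonscar_bad_mask", "`%s` contains NA", arg)
  }
  invisible(mask)
}

check_same_shape <- function(a, b, what = "image and mask") {
  if (!identical(dim(a), dim(b))) {
    rs_stop("radonscar_shape_mismatch", "%s must have identical dimensions", what)
  }
  invisible(NULL)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b Logical matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  check_mask(a, "a"); check_mask(b, "b")
  check_same_shape(a, b, "the two masks")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
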