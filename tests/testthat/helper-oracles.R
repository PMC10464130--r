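# Fixture generators and independent brute-force oracles used across tests.

random_image <- function(h, w = h, lo = 0, hu = 200) {
  matrix(stats::runif(h * w, lo, hu), h, w)
}

random_mask <- function(h, w = h, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}

# --- region statistics: plain double loop --------------------------------
oracle_region_stats <- function(image, mask) {
  vals <- c()
  for (r in seq_len(nrow(image))) {
    for (cc in seq_len(ncol(image))) {
      if (mask[r, cc]) vals <- c(vals, image[r, cc])
    }
  }
  m <- sum(vals) / length(vals)
  list(mean = m, sd = sqrt(sum((vals - m)^2) / length(vals)), n = length(vals))
}

# --- region growing: component labeling on the admissible lattice --------
oracle_region_grow <- function(image, seed, tolerance) {
  admissible <- abs(image - image[seed[1], seed[2]]) <= tolerance
  h <- nrow(image); w <- ncol(image)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!admissible[r, cc] || lab[r, cc] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r, cc))
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > h || p[2] < 1 || p[2] > w) next
      if (!admissible[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- cur
      stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                 list(p + c(0, 1)), list(p - c(0, 1)))
    }
  }
  lab == lab[seed[1], seed[2]]
}

# --- morphology: direct per-pixel definition -----------------------------
oracle_erode <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    ok <- TRUE
    for (i in seq_len(nrow(se))) {
      rr <- r + se[i, 1]; c2 <- cc + se[i, 2]
      inside <- rr >= 1 && rr <= h && c2 >= 1 && c2 <= w
      if (!inside || !mask[rr, c2]) { ok <- FALSE; break }
    }
    out[r, cc] <- ok
  }
  out
}

# --- Radon: per-pixel bilinear accumulation onto offset bins -------------
oracle_radon <- function(m, angles) {
  n <- nrow(m)
  p <- radonscar:::radon_pad_size(n)
  off <- (p - n) %/% 2
  ctr <- (p + 1) / 2
  out <- matrix(0, p, length(angles))
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    for (r in seq_len(n)) for (cc in seq_len(n)) {
      t_off <- ctr - (r + off - ctr) * sin(th) + (cc + off - ctr) * cos(th)
      b0 <- floor(t_off); fr <- t_off - b0
      if (b0 >= 1 && b0 <= p) out[b0, a] <- out[b0, a] + m[r, cc] * (1 - fr)
      if (b0 + 1 <= p && b0 + 1 >= 1) out[b0 + 1, a] <- out[b0 + 1, a] + m[r, cc] * fr
    }
  }
  out
}

# --- LBP: bit-by-bit enumeration -----------------------------------------
oracle_lbp_code <- function(center, neighbors) {
  code <- 0L
  for (i in 0:7) {
    if (neighbors[i + 1] >= center) code <- code + bitwShiftL(1L, i)
  }
  code
}

oracle_riu2 <- function(code) {
  bits <- integer(8)
  for (i in 0:7) bits[i + 1] <- (code %/% 2^i) %% 2
  trans <- 0L
  for (i in 1:8) if (bits[i] != bits[if (i == 8) 1 else i + 1]) trans <- trans + 1L
  if (trans <= 2L) as.integer(sum(bits)) else 9L
}

oracle_lbp_feature <- function(image) {
  h <- nrow(image); w <- ncol(image)
  counts <- integer(10)
  # neighbour order must mirror the documented E, NE, N, NW, W, SW, S, SE
  drs <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dcs <- c(1, 1, 0, -1, -1, -1, 0, 1)
  for (r in 2:(h - 1)) for (cc in 2:(w - 1)) {
    nb <- numeric(8)
    for (i in 1:8) nb[i] <- image[r + drs[i], cc + dcs[i]]
    lab <- oracle_riu2(oracle_lbp_code(image[r, cc], nb))
    counts[lab + 1] <- counts[lab + 1] + 1L
  }
  counts / sum(counts)
}

# --- 1-D Wasserstein by inverse-CDF (quantile) coupling ------------------
oracle_wasserstein <- function(p, q) {
  cp <- cumsum(p); cq <- cumsum(q)
  us <- sort(unique(c(0, cp, cq)))
  total <- 0
  for (i in seq_len(length(us) - 1)) {
    mid <- (us[i] + us[i + 1]) / 2
    qp <- which(cp >= mid - 1e-15)[1]
    qq <- which(cq >= mid - 1e-15)[1]
    total <- total + abs(qp - qq) * (us[i + 1] - us[i])
  }
  total
}

random_histogram <- function(n = 10) {
  x <- stats::rgamma(n, shape = 0.7)
  x / sum(x)
}

# Balanced two-class feature set drawn from one distribution (null data):
# patches all come from healthy myocardium; labels are arbitrary.
null_feature_set <- function(n_per_class = 100, seed = 1L, angles = 0:179) {
  ph <- generate_phantom(phantom_spec(seed = seed))
  normal_region <- ph$myocardium & !ph$scar
  pa <- extract_patches(ph$image, normal_region, "scar", n_per_class,
                        seed = seed + 1L)
  pb <- extract_patches(ph$image, normal_region, "normal", n_per_class,
                        seed = seed + 2L)
  patch_features(c(pa, pb), angles = angles)
}
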