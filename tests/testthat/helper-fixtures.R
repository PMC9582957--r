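# shared fixture builders; everything is generated in code at test time

# named 8-band coverage vector in canonical order
cov8 <- function(ant = c(0, 0, 0, 0), post = c(0, 0, 0, 0)) {
  stats::setNames(c(ant, post),
                  c("L1_anterior", "L2_anterior", "L3_anterior", "L4_anterior",
                    "L1_posterior", "L2_posterior", "L3_posterior",
                    "L4_posterior"))
}

# noise-free phantom config (geometry identical to the default)
clean_config <- function(...) {
  phantom_config(noise_sd = 0, speckle_sd = 0, ...)
}

# ground-truth 3-class label mask for segmenter training
truth_label_mask <- function(phantom) {
  m <- matrix(0L, nrow(phantom$image$pixels), ncol(phantom$image$pixels))
  m[phantom$truth$pelvis_mask] <- 1L
  m[phantom$truth$vertebra_mask] <- 2L
  m
}

# cheap content checksum for determinism checks
digest_sum <- function(m) c(dim(m), sum(m), sum(m^2))

# independent brute-force Kauppila oracle: explicit loops over rows and
# walls, scoring with literal if-else thresholds
oracle_kauppila <- function(mask, roi, eps = 0.02) {
  total <- 0L
  for (i in seq_len(nrow(roi$levels))) {
    lev <- roi$levels$level[i]
    r0 <- roi$levels$row_min[i]; r1 <- roi$levels$row_max[i]
    h <- roi$levels$height[i]
    for (w in c("anterior", "posterior")) {
      hit <- 0L
      for (r in r0:r1) {
        b <- roi$bands[roi$bands$level == lev & roi$bands$row == r, ]
        lo <- if (w == "anterior") b$ant_lo else b$post_lo
        hi <- if (w == "anterior") b$ant_hi else b$post_hi
        lo <- max(1L, lo); hi <- min(ncol(mask), hi)
        if (hi >= lo && any(mask[r, lo:hi])) hit <- hit + 1L
      }
      f <- hit / h
      s <- if (f <= eps) 0L else if (f < 1 / 3) 1L else if (f <= 2 / 3) 2L else 3L
      total <- total + s
    }
  }
  total
}

# paint a random calcification mask inside the ROI bands
random_roi_mask <- function(roi, dim, p = 0.08) {
  bands <- roi_masks(roi, dim)
  m <- matrix(FALSE, dim[1], dim[2])
  for (b in bands) {
    idx <- which(b)
    on <- idx[stats::runif(length(idx)) < p]
    m[on] <- TRUE
  }
  m
}
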