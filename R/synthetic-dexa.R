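#' Phantom configuration
#'
#' Parameters of the lateral-DEXA-like phantom generator. The phantom places
#' four lumbar vertebrae (L1-L4) and a pelvis blob along a quadratic spine
#' curve, then renders calcific deposits in an aortic band anterior to the
#' curve. Geometry defaults (`offset_factor`, `width_factor`) are shared with
#' [extract_aortic_roi()] so the rule-based pipeline and the generator agree
#' on where the aorta lies.
#'
#' @param rows,cols image grid size in pixels.
#' @param spacing_mm pixel spacing (isotropic).
#' @param vert_height_range integer range the four vertebral heights are
#'   drawn from (pixels).
#' @param vert_width vertebral body width in pixels.
#' @param gap intervertebral gap in pixels.
#' @param top_row row of the superior edge of L1.
#' @param curve quadratic spine-curve coefficients `c(c0, c1, c2)` mapping
#'   centred row `r - rows/2` to column: `col = c0 + c1*(r-m) + c2*(r-m)^2`.
#' @param offset_factor aortic band offset anterior to the spine curve, as a
#'   multiple of mean vertebral height.
#' @param width_factor aortic band width as a multiple of mean vertebral
#'   height.
#' @param deposit_halfwidth half-thickness of a calcific streak in pixels
#'   (thickness `2*deposit_halfwidth + 1`).
#' @param background,field_amp soft-tissue base intensity and amplitude of a
#'   smooth low-frequency background field.
#' @param vert_amp,pelvis_amp,calc_amp intensity of vertebrae, pelvis and
#'   calcific deposits above background (0-1 scale).
#' @param contrast_L12 multiplier in (0, 1] applied to deposit intensity at
#'   L1 and L2, emulating the reduced conspicuity of calcification behind
#'   the lower ribs and bowel gas in the upper lumbar region.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param speckle_sd multiplicative (speckle) noise standard deviation.
#' @param coverage either `NULL` (sample per-wall coverage fractions from the
#'   skewed prevalence model, see [sample_coverage()]) or a named numeric
#'   vector/list over `L1_anterior` ... `L4_posterior` with values in 0-1.
#' @param seed integer seed making the phantom fully reproducible.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(rows = 160, cols = 96, spacing_mm = 1,
                           vert_height_range = c(16L, 20L),
                           vert_width = 16, gap = 4, top_row = 16,
                           curve = c(30, 0.08, 0.002),
                           offset_factor = 1.2, width_factor = 0.8,
                           deposit_halfwidth = 1,
                           background = 0.10, field_amp = 0.03,
                           vert_amp = 0.75, pelvis_amp = 0.70,
                           calc_amp = 0.75, contrast_L12 = 0.6,
                           noise_sd = 0.03, speckle_sd = 0.02,
                           coverage = NULL, seed = 1L) {
  cfg <- list(rows = rows, cols = cols, spacing_mm = spacing_mm,
              vert_height_range = vert_height_range, vert_width = vert_width,
              gap = gap, top_row = top_row, curve = curve,
              offset_factor = offset_factor, width_factor = width_factor,
              deposit_halfwidth = deposit_halfwidth,
              background = background, field_amp = field_amp,
              vert_amp = vert_amp, pelvis_amp = pelvis_amp,
              calc_amp = calc_amp, contrast_L12 = contrast_L12,
              noise_sd = noise_sd, speckle_sd = speckle_sd,
              coverage = coverage, seed = seed)
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$rows < 64 || cfg$cols < 32)
    abort_aac("phantom grid must be at least 64 x 32", "aac_config_error")
  if (!is.null(cfg$coverage)) {
    cov <- unlist(cfg$coverage)
    if (!all(wall_keys() %in% names(cov)))
      abort_aac(paste("coverage must name all 8 bands:",
                      paste(wall_keys(), collapse = ", ")),
                "aac_validation_error")
    if (any(cov < 0 | cov > 1))
      abort_aac("coverage fractions must lie in [0, 1]",
                "aac_validation_error")
  }
  if (cfg$contrast_L12 <= 0 || cfg$contrast_L12 > 1)
    abort_aac("contrast_L12 must be in (0, 1]", "aac_validation_error")
  ## worst-case vertical extent: 4 vertebrae + gaps + pelvis
  need <- cfg$top_row + 4 * max(cfg$vert_height_range) + 3 * cfg$gap + 6 + 28
  if (need > cfg$rows)
    abort_aac(sprintf(
      "image too small for 4 vertebrae and pelvis (needs >= %d rows)", need),
      "aac_config_error")
  invisible(cfg)
}

## spine-curve column at (absolute) row r for a config
phantom_curve_col <- function(cfg, r) {
  m <- cfg$rows / 2
  cfg$curve[1] + cfg$curve[2] * (r - m) + cfg$curve[3] * (r - m)^2
}

## same curve re-expressed in the absolute-row basis used by fit_spine_curve
phantom_curve_abs <- function(cfg) {
  m <- cfg$rows / 2
  c(cfg$curve[1] - cfg$curve[2] * m + cfg$curve[3] * m^2,
    cfg$curve[2] - 2 * cfg$curve[3] * m,
    cfg$curve[3])
}

#' Sample per-wall coverage fractions from the skewed prevalence model
#'
#' Most scans carry little or no calcification: an image is "affected" with
#' probability 0.55; within an affected image each wall is involved with a
#' per-level probability rising from L1 to L4 (0.12, 0.15, 0.30, 0.35),
#' reflecting that scores are driven by the L3-L4 region; involved walls draw
#' their coverage from Beta(1, 3.5). Under these frozen constants about 79%
#' of phantom totals fall below 3 and about 11% exceed 3.
#'
#' @param p_affected probability an image carries any calcification.
#' @param p_wall per-level involvement probabilities (L1..L4), recycled over
#'   both walls.
#' @param shape1,shape2 Beta parameters of the coverage fraction of an
#'   involved wall.
#' @return Named numeric vector of 8 coverage fractions.
#' @export
sample_coverage <- function(p_affected = 0.55,
                            p_wall = c(0.12, 0.15, 0.30, 0.35),
                            shape1 = 1, shape2 = 3.5) {
  keys <- wall_keys()
  f <- setNames(numeric(8L), keys)
  if (runif(1) < p_affected) {
    lev_p <- rep(p_wall, times = 2L)  # anterior block then posterior block
    hit <- runif(8L) < lev_p
    f[hit] <- rbeta(sum(hit), shape1, shape2)
  }
  f
}

#' Generate one synthetic lateral-DEXA phantom
#'
#' Renders the phantom described by `config` and returns both the image and
#' an exact ground-truth record. The projected extent of each deposit along
#' its vertebra equals the requested coverage fraction times the vertebral
#' height to within one pixel; the `coverage` field of the ground truth
#' stores the *realized* (pixel-quantized) fraction, and `true_score` is the
#' Kauppila rule applied to that realized coverage.
#'
#' @param config a [phantom_config].
#' @return A list with elements `image` (a [dexa_image]) and `truth`, where
#'   `truth` contains `vertebrae` (box table), `pelvis_mask`,
#'   `vertebra_mask`, `calc_mask`, `aorta_centerline`, `coverage`,
#'   `requested_coverage`, `true_score` (a [kauppila_score()] object),
#'   `contrast_L12`, `curve_coef` (absolute-row basis), `offset_px`,
#'   `width_px`.
#' @examples
#' ph <- generate_phantom(phantom_config(noise_sd = 0, speckle_sd = 0,
#'   coverage = c(L1_anterior = 0, L2_anterior = 0.5, L3_anterior = 0,
#'                L4_anterior = 0, L1_posterior = 0, L2_posterior = 0,
#'                L3_posterior = 0, L4_posterior = 0)))
#' ph$truth$true_score$total
#' @export
generate_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  cfg <- config
  local_seed(cfg$seed, {
    nr <- cfg$rows; nc <- cfg$cols
    img <- matrix(cfg$background, nr, nc)

    ## low-frequency background field (smooth, seeded phases)
    ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
    field <- cfg$field_amp *
      outer(sin(2 * pi * seq_len(nr) / nr + ph1),
            cos(2 * pi * seq_len(nc) / nc + ph2))
    img <- img + field

    ## vertebral boxes along the curve, superior -> inferior
    hrange <- cfg$vert_height_range
    hts <- if (hrange[1] == hrange[2]) rep(hrange[1], 4L)
           else sample(seq(hrange[1], hrange[2]), 4L, replace = TRUE)
    start <- cfg$top_row
    boxes <- vector("list", 4L)
    vert_mask <- matrix(FALSE, nr, nc)
    for (i in 1:4) {
      r0 <- start; r1 <- start + hts[i] - 1L
      rc <- (r0 + r1) / 2
      cc <- phantom_curve_col(cfg, rc)
      c0 <- round(cc - cfg$vert_width / 2); c1 <- round(cc + cfg$vert_width / 2)
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + cfg$vert_amp
      vert_mask[r0:r1, c0:c1] <- TRUE
      boxes[[i]] <- data.frame(level = aac_levels[i], row_min = r0,
                               row_max = r1, col_min = c0, col_max = c1,
                               centroid_row = rc, centroid_col = (c0 + c1) / 2,
                               height = hts[i])
      start <- r1 + 1L + cfg$gap
    }
    boxes <- do.call(rbind, boxes)

    ## pelvis: large ellipse below L4
    pr <- start + 6 + 14
    pc <- phantom_curve_col(cfg, pr) + 4
    rr <- matrix(seq_len(nr), nr, nc)
    ccm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    pelvis_mask <- ((rr - pr) / 14)^2 + ((ccm - pc) / 30)^2 <= 1
    pelvis_mask[, ] <- pelvis_mask & rr >= 1 & ccm >= 1
    img[pelvis_mask] <- img[pelvis_mask] + cfg$pelvis_amp

    ## aortic band geometry shared with the ROI extractor
    hbar <- mean(hts)
    offset_px <- cfg$offset_factor * hbar
    width_px <- cfg$width_factor * hbar

    ## coverage: requested (possibly sampled) and realized after pixelation
    f_req <- if (is.null(cfg$coverage)) sample_coverage()
             else unlist(cfg$coverage)[wall_keys()]
    f_real <- setNames(numeric(8L), wall_keys())
    calc_mask <- matrix(FALSE, nr, nc)
    for (i in 1:4) {
      lev <- aac_levels[i]
      b <- boxes[boxes$level == lev, ]
      h <- b$height
      for (w in aac_walls) {
        key <- paste(lev, w, sep = "_")
        len <- round(f_req[[key]] * h)
        f_real[key] <- len / h
        if (len == 0) next
        dep_r0 <- b$row_min + sample.int(h - len + 1L, 1L) - 1L
        dep_rows <- dep_r0:(dep_r0 + len - 1L)
        amp <- cfg$calc_amp * if (lev %in% c("L1", "L2")) cfg$contrast_L12 else 1
        for (r in dep_rows) {
          ctr <- phantom_curve_col(cfg, r) + offset_px +
            if (w == "posterior") -width_px / 4 else width_px / 4
          cc0 <- max(1L, round(ctr) - cfg$deposit_halfwidth)
          cc1 <- min(nc, round(ctr) + cfg$deposit_halfwidth)
          img[r, cc0:cc1] <- img[r, cc0:cc1] + amp
          calc_mask[r, cc0:cc1] <- TRUE
        }
      }
    }

    ## noise: multiplicative speckle then additive Gaussian
    if (cfg$speckle_sd > 0)
      img <- img * (1 + matrix(rnorm(nr * nc, 0, cfg$speckle_sd), nr, nc))
    if (cfg$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
    img <- pmax(img, 0)

    center_rows <- boxes$row_min[1]:boxes$row_max[4]
    centerline <- data.frame(
      row = center_rows,
      col = phantom_curve_col(cfg, center_rows) + offset_px)

    truth <- list(
      vertebrae = boxes,
      pelvis_mask = pelvis_mask,
      vertebra_mask = vert_mask,
      calc_mask = calc_mask,
      aorta_centerline = centerline,
      coverage = f_real,
      requested_coverage = f_req,
      true_score = kauppila_score(f_real),
      contrast_L12 = cfg$contrast_L12,
      curve_coef = phantom_curve_abs(cfg),
      offset_px = offset_px,
      width_px = width_px)

    list(image = dexa_image(img, spacing_mm = cfg$spacing_mm,
                            id = sprintf("phantom_seed%d", cfg$seed)),
         truth = truth)
  })
}

#' Generate a set of phantoms
#'
#' Produces `n` phantoms from a config template, re-seeding each phantom
#' deterministically from `seed` and (unless the template fixes `coverage`)
#' sampling per-wall coverage from the skewed prevalence model so that the
#' score distribution is dominated by low totals.
#'
#' @param n number of phantoms (`n = 0` returns an empty list).
#' @param config template [phantom_config]; its `seed` and `coverage` are
#'   overridden per image.
#' @param seed integer master seed.
#' @return List of length `n`; each element as returned by
#'   [generate_phantom()].
#' @export
generate_image_set <- function(n, config = phantom_config(), seed = 1L) {
  if (n < 0) abort_aac("n must be non-negative", "aac_validation_error")
  if (n == 0) return(list())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    out[[i]] <- generate_phantom(cfg)
    out[[i]]$image$id <- sprintf("phantom_%04d", i)
  }
  out
}

#' Write a phantom (image + ground-truth sidecar) to disk
#'
#' The image is written as 16-bit TIFF (or 8-bit PNG) and the ground truth as a
#' JSON sidecar `<image>.truth.json` with a schema version; masks are stored
#' as run-length-free row/col index lists to keep sidecars plain text.
#'
#' @param phantom element as returned by [generate_phantom()].
#' @param dir output directory (created if missing).
#' @param format `"tiff"` (16-bit) or `"png"` (8-bit).
#' @return Invisibly, the image path.
#' @export
write_phantom <- function(phantom, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "png") "png" else "tif"
  img_path <- file.path(dir, paste0(phantom$image$id, ".", ext))
  write_dexa(phantom$image, img_path)
  tr <- phantom$truth
  sidecar <- list(
    schema_version = "1.0",
    image_id = phantom$image$id,
    vertebrae = tr$vertebrae,
    coverage = as.list(tr$coverage),
    true_score = list(walls = as.list(tr$true_score$walls),
                      total = tr$true_score$total),
    contrast_L12 = tr$contrast_L12,
    curve_coef = tr$curve_coef,
    offset_px = tr$offset_px,
    width_px = tr$width_px,
    calc_pixels = which(tr$calc_mask, arr.ind = TRUE))
  jsonlite::write_json(sidecar, file.path(dir, paste0(phantom$image$id,
                                                      ".truth.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(img_path)
}
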