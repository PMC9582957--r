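#' Fit a smooth spine curve through vertebral centroids
#'
#' Least-squares polynomial (default quadratic, capturing the single lumbar
#' lordosis bend) mapping row to column, fitted through the four vertebral
#' centroids and, optionally, the pelvis centroid as an inferior anchor.
#'
#' @param boxes a `vertebra_boxes` table from [detect_vertebrae()].
#' @param pelvis_centroid optional `c(row, col)` anchor. The pelvis centroid
#'   sits anterior to the spine axis, so anchoring on it biases the
#'   curvature estimate; it is therefore only used when passed explicitly
#'   (useful when fewer than 3 vertebrae were detected).
#' @param degree polynomial degree; must be smaller than the number of
#'   distinct fit rows. Degenerate inputs (too few distinct rows) fall back
#'   to degree 1 with a warning.
#' @return Object of class `spine_curve`: `coef` (ascending powers of the
#'   absolute row index), `degree`, `domain` (row range covered by the
#'   boxes).
#' @export
fit_spine_curve <- function(boxes, pelvis_centroid = NULL, degree = 2) {
  stopifnot(inherits(boxes, "vertebra_boxes") || is.data.frame(boxes))
  rows <- boxes$centroid_row
  cols <- boxes$centroid_col
  if (!is.null(pelvis_centroid)) {
    rows <- c(rows, pelvis_centroid[1])
    cols <- c(cols, pelvis_centroid[2])
  }
  n_distinct <- length(unique(rows))
  if (degree >= length(rows))
    abort_aac(sprintf("degree %d requires more than %d points",
                      degree, length(rows)), "aac_validation_error")
  if (degree >= n_distinct) {
    warning("degenerate (coincident-row) centroids: falling back to degree 1")
    degree <- max(1L, n_distinct - 1L)
  }
  X <- outer(rows, 0:degree, "^")
  cf <- qr.solve(X, cols)
  curve <- structure(list(coef = cf, degree = degree,
                          domain = c(min(boxes$row_min), max(boxes$row_max))),
                     class = "spine_curve")
  ## sanity: curve should pass near every centroid
  res <- abs(curve_col(curve, boxes$centroid_row) - boxes$centroid_col)
  widths <- boxes$col_max - boxes$col_min + 1
  if (any(res > widths / 4))
    warning(sprintf("spine-curve residual up to %.1f px exceeds 1/4 of the vertebral width",
                    max(res)))
  curve
}

#' Evaluate a spine curve at given rows
#'
#' @param curve a `spine_curve`.
#' @param rows numeric vector of row indices.
#' @return Column positions.
#' @export
curve_col <- function(curve, rows) {
  drop(outer(rows, 0:curve$degree, "^") %*% curve$coef)
}

#' Extract the aortic region of interest anterior to the spine curve
#'
#' For each vertebral level a band is placed anterior (increasing column) to
#' the spine curve at `offset_factor` times the mean vertebral height, with
#' width `width_factor` times the mean vertebral height, spanning exactly
#' that vertebra's row range. The band is split at its midline: the
#' spine-adjacent half is the posterior wall sub-band, the far half the
#' anterior wall sub-band. This midline split is the package's operational
#' definition of the two aortic walls in lateral projection.
#'
#' @param curve a `spine_curve` whose domain covers all boxes.
#' @param boxes a `vertebra_boxes` table.
#' @param offset_factor,width_factor band geometry as multiples of mean
#'   vertebral height; defaults shared with [phantom_config()].
#' @param image_dim optional `c(rows, cols)`; bands exceeding the columns
#'   are clipped with a warning, and a fully out-of-bounds band raises a
#'   localization failure.
#' @return Object of class `aortic_roi`: `bands` (one row per image row per
#'   level: integer column ranges `post_lo:post_hi` and `ant_lo:ant_hi`),
#'   `offset_px`, `width_px`, `levels` (per-level row ranges).
#' @export
extract_aortic_roi <- function(curve, boxes, offset_factor = 1.2,
                               width_factor = 0.8, image_dim = NULL) {
  stopifnot(inherits(curve, "spine_curve"))
  if (curve$domain[1] > min(boxes$row_min) ||
      curve$domain[2] < max(boxes$row_max))
    abort_aac("spine-curve domain does not cover the vertebral boxes",
              "aac_validation_error")
  if (offset_factor == 0)
    warning("offset factor 0: aortic band abuts the spine")
  hbar <- mean(boxes$height)
  offset_px <- offset_factor * hbar
  width_px <- width_factor * hbar

  bands <- do.call(rbind, lapply(seq_len(nrow(boxes)), function(i) {
    rows <- boxes$row_min[i]:boxes$row_max[i]
    ctr <- curve_col(curve, rows) + offset_px
    data.frame(level = boxes$level[i], row = rows,
               post_lo = round(ctr - width_px / 2),
               post_hi = round(ctr) - 1L,
               ant_lo = round(ctr),
               ant_hi = round(ctr + width_px / 2))
  }))

  if (!is.null(image_dim)) {
    nc <- image_dim[2]
    if (all(bands$post_lo > nc) || all(bands$ant_hi < 1))
      abort_aac("aortic band lies fully outside the image",
                "aac_localization_error")
    if (any(bands$ant_hi > nc) || any(bands$post_lo < 1)) {
      warning("aortic band clipped at image bounds")
      bands$post_lo <- pmax(bands$post_lo, 1L)
      bands$post_hi <- pmin(pmax(bands$post_hi, 1L), nc)
      bands$ant_lo <- pmin(pmax(bands$ant_lo, 1L), nc)
      bands$ant_hi <- pmin(bands$ant_hi, nc)
    }
  }

  levels_df <- data.frame(level = boxes$level, row_min = boxes$row_min,
                          row_max = boxes$row_max, height = boxes$height)
  structure(list(bands = bands, offset_px = offset_px, width_px = width_px,
                 levels = levels_df,
                 offset_factor = offset_factor, width_factor = width_factor),
            class = "aortic_roi")
}

#' Rasterize an aortic ROI into per-wall logical masks
#'
#' @param roi an `aortic_roi`.
#' @param dim image dimensions `c(rows, cols)`.
#' @return Named list over the 8 `level_wall` keys of logical matrices.
#' @export
roi_masks <- function(roi, dim) {
  out <- setNames(vector("list", 8L), wall_keys())
  for (k in wall_keys()) out[[k]] <- matrix(FALSE, dim[1], dim[2])
  for (i in seq_len(nrow(roi$bands))) {
    b <- roi$bands[i, ]
    if (b$post_hi >= b$post_lo) {
      cols <- max(1L, b$post_lo):min(dim[2], b$post_hi)
      out[[paste(b$level, "posterior", sep = "_")]][b$row, cols] <- TRUE
    }
    if (b$ant_hi >= b$ant_lo) {
      cols <- max(1L, b$ant_lo):min(dim[2], b$ant_hi)
      out[[paste(b$level, "anterior", sep = "_")]][b$row, cols] <- TRUE
    }
  }
  out
}

#' Export an ROI as a JSON polygon set
#'
#' One closed polygon per (level, wall) sub-band, in row/column pixel
#' coordinates, suitable for overlay QC.
#'
#' @param roi an `aortic_roi`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roi, path) {
  polys <- lapply(split(roi$bands, roi$bands$level), function(b) {
    list(
      posterior = list(rows = c(b$row, rev(b$row)),
                       cols = c(b$post_lo, rev(b$post_hi))),
      anterior = list(rows = c(b$row, rev(b$row)),
                      cols = c(b$ant_lo, rev(b$ant_hi))))
  })
  jsonlite::write_json(list(schema_version = "1.0",
                            offset_px = roi$offset_px,
                            width_px = roi$width_px,
                            polygons = polys),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
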