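#' Segment the lower spine (pelvis + lumbar vertebrae)
#'
#' Two interchangeable back-ends produce the same `spine_segmentation`
#' object. The `classical` back-end thresholds the bright skeletal
#' structures (Otsu's method restricted to the upper intensity quartile),
#' applies a morphological opening that removes thin calcific streaks, and
#' labels connected components; it is fully deterministic. The `learned`
#' back-end applies a trained pixel classifier (see [train_segmenter()]) and
#' then the same morphological cleanup.
#'
#' The largest retained component is taken as the pelvis; every other
#' component is assigned the vertebra class.
#'
#' @param image a [dexa_image].
#' @param method `"classical"` or `"learned"`.
#' @param model a `spine_seg_model` from [train_segmenter()] (required for
#'   the learned method).
#' @param min_area components smaller than this many pixels are discarded.
#' @param brush_size diameter of the disc brush used for the opening.
#' @return An object of class `spine_segmentation`: `mask` (integer matrix,
#'   0 background / 1 pelvis / 2 vertebra), `components` (one row per
#'   component: label, class, area, centroid and bounding box) and `method`.
#'   Images in which no skeletal component is found raise a classed
#'   localization failure (`aac_localization_error`) so that batch drivers
#'   can skip and report them.
#' @export
segment_spine <- function(image, method = c("classical", "learned"),
                          model = NULL, min_area = 40, brush_size = 5) {
  method <- match.arg(method)
  stopifnot(inherits(image, "dexa_image"))
  px <- image$pixels

  fg <- if (method == "classical") {
    upper <- px[px >= quantile(px, 0.75)]
    if (length(unique(round(upper, 6))) < 2L)
      abort_aac("no intensity contrast: cannot locate spine",
                "aac_localization_error")
    thr <- EBImage::otsu(EBImage::Image(matrix(upper, ncol = 1)),
                         range = range(upper))
    px > thr
  } else {
    if (is.null(model) || !inherits(model, "spine_seg_model"))
      abort_aac("learned segmentation requires a trained spine_seg_model",
                "aac_config_error")
    pred <- predict_seg_pixels(model, px)
    pred > 0L
  }

  opened <- EBImage::opening(fg, EBImage::makeBrush(brush_size, "disc"))
  labels <- EBImage::bwlabel(opened)
  lab <- as.integer(labels)
  areas <- tabulate(lab)
  keep <- which(areas >= min_area)
  if (length(keep) == 0L)
    abort_aac("no spine component found after filtering",
              "aac_localization_error")

  comp <- do.call(rbind, lapply(keep, function(k) {
    idx <- which(matrix(lab, nrow(px), ncol(px)) == k, arr.ind = TRUE)
    data.frame(label = k, area = nrow(idx),
               centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]),
               row_min = min(idx[, 1]), row_max = max(idx[, 1]),
               col_min = min(idx[, 2]), col_max = max(idx[, 2]))
  }))
  pelvis_label <- comp$label[which.max(comp$area)]
  comp$class <- ifelse(comp$label == pelvis_label, "pelvis", "vertebra")

  mask <- matrix(0L, nrow(px), ncol(px))
  labm <- matrix(lab, nrow(px), ncol(px))
  mask[labm == pelvis_label] <- 1L
  mask[labm %in% comp$label[comp$class == "vertebra"]] <- 2L

  structure(list(mask = mask, components = comp, method = method),
            class = "spine_segmentation")
}

#' @export
print.spine_segmentation <- function(x, ...) {
  cat(sprintf("<spine_segmentation> method=%s, %d component(s): %s\n",
              x$method, nrow(x$components),
              paste(sprintf("%s(%dpx)", x$components$class,
                            x$components$area), collapse = ", ")))
  invisible(x)
}

#' Detect the four lumbar vertebrae as labeled boxes
#'
#' Vertebra-class components superior to the pelvis centroid are ranked by
#' area; the four largest are kept (extra bright distractors are dropped
#' with a message) and labeled L1-L4 counting downward from the most
#' superior box, i.e. upward from the pelvis anchor.
#'
#' @param x a `spine_segmentation` or a [dexa_image] (which is segmented
#'   first with the given method/model).
#' @param method,model forwarded to [segment_spine()] when `x` is an image.
#' @return A `data.frame` of class `vertebra_boxes` with one row per level
#'   (`L1` superior to `L4`): bounding box, centroid and height in pixels.
#' @export
detect_vertebrae <- function(x, method = "classical", model = NULL) {
  seg <- if (inherits(x, "dexa_image"))
    segment_spine(x, method = method, model = model) else x
  if (!inherits(seg, "spine_segmentation"))
    abort_aac("x must be a dexa_image or spine_segmentation",
              "aac_validation_error")
  comp <- seg$components
  pelvis <- comp[comp$class == "pelvis", ]
  verts <- comp[comp$class == "vertebra", ]
  if (nrow(pelvis) == 1L)
    verts <- verts[verts$centroid_row < pelvis$centroid_row, ]
  if (nrow(verts) < 4L)
    abort_aac(sprintf("found %d vertebra candidate(s); need 4", nrow(verts)),
              "aac_localization_error")
  if (nrow(verts) > 4L) {
    message(sprintf("dropping %d small distractor component(s)",
                    nrow(verts) - 4L))
    verts <- verts[order(verts$area, decreasing = TRUE)[1:4], ]
  }
  verts <- verts[order(verts$centroid_row), ]
  boxes <- data.frame(level = aac_levels,
                      row_min = verts$row_min, row_max = verts$row_max,
                      col_min = verts$col_min, col_max = verts$col_max,
                      centroid_row = verts$centroid_row,
                      centroid_col = verts$centroid_col,
                      height = verts$row_max - verts$row_min + 1L)
  attr(boxes, "pelvis_centroid") <-
    if (nrow(pelvis) == 1L) c(pelvis$centroid_row, pelvis$centroid_col)
    else NULL
  class(boxes) <- c("vertebra_boxes", "data.frame")
  boxes
}

## pixel feature matrix for the learned segmenter: raw intensity, two
## Gaussian-smoothed scales, normalized row/column position
seg_pixel_features <- function(px) {
  s2 <- as.matrix(EBImage::gblur(px, sigma = 2))
  s4 <- as.matrix(EBImage::gblur(px, sigma = 4))
  nr <- nrow(px); nc <- ncol(px)
  cbind(intensity = as.vector(px),
        smooth2 = as.vector(s2),
        smooth4 = as.vector(s4),
        row_pos = rep(seq_len(nr) / nr, times = nc),
        col_pos = rep(seq_len(nc) / nc, each = nr))
}

predict_seg_pixels <- function(model, px) {
  feat <- seg_pixel_features(px)
  feat <- scale(feat, center = model$center, scale = model$scale)
  p <- predict(model$fit, feat)              # softmax posteriors
  cls <- max.col(p) - 1L                     # 0 bg, 1 pelvis, 2 vertebra
  matrix(cls, nrow(px), ncol(px))
}

#' Train the learned spine segmenter
#'
#' Fits a small single-hidden-layer neural network pixel classifier
#' (background / pelvis / vertebra) on paired phantom images and label
#' masks, using intensity at three scales plus normalized position as
#' features. A stratified subsample of pixels per image keeps training
#' desk-scale.
#'
#' @param images list of [dexa_image] objects.
#' @param masks list of integer label matrices (0 background, 1 pelvis, 2
#'   vertebra), same grids as the images.
#' @param size hidden units.
#' @param decay weight decay.
#' @param maxit training iterations.
#' @param pixels_per_image pixels subsampled per training image.
#' @param seed RNG seed for subsampling and weight initialization.
#' @return An object of class `spine_seg_model` usable with
#'   [segment_spine()] (`method = "learned"`); serialize with
#'   [write_model()].
#' @export
train_segmenter <- function(images, masks, size = 6, decay = 1e-3,
                            maxit = 150, pixels_per_image = 1200, seed = 1L) {
  if (length(images) != length(masks))
    abort_aac("images and masks must have equal length", "aac_validation_error")
  if (length(images) < 1L)
    abort_aac("at least one training pair is required", "aac_validation_error")
  if (length(images) < 50L)
    message(sprintf(
      "degenerate training set: %d pair(s) (< 50); model quality not assured",
      length(images)))
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]$pixels), dim(masks[[i]])))
      abort_aac(sprintf("image/mask shape mismatch at pair %d", i),
                "aac_validation_error")
  }
  local_seed(seed, {
    feats <- list(); labs <- list()
    for (i in seq_along(images)) {
      f <- seg_pixel_features(images[[i]]$pixels)
      y <- as.integer(masks[[i]])
      ## stratified subsample: keep minority classes represented
      idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
        sample(ix, min(length(ix), ceiling(pixels_per_image / 3)))
      }))
      feats[[i]] <- f[idx, , drop = FALSE]
      labs[[i]] <- y[idx]
    }
    x <- do.call(rbind, feats)
    y <- unlist(labs)
    ctr <- colMeans(x); scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    yy <- nnet::class.ind(factor(y, levels = 0:2))
    fit <- nnet::nnet(xs, yy, size = size, decay = decay, maxit = maxit,
                      softmax = TRUE, trace = FALSE, MaxNWts = 5000)
    structure(list(fit = fit, center = ctr, scale = scl,
                   classes = 0:2, format_version = "1.0",
                   n_train = length(images)),
              class = "spine_seg_model")
  })
}

#' Serialize / restore model handles
#'
#' Model handles (`spine_seg_model`, `aac_regressor`) are written to a
#' single RDS file carrying a `format_version` field.
#'
#' @param model a model handle.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` the handle.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  if (is.null(m$format_version))
    abort_aac("file does not contain an aacquant model handle",
              "aac_validation_error")
  m
}

#' Dice coefficient between two binary masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return Dice similarity in 0-1 (1 if both masks are empty).
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
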