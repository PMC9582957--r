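#' Detect calcification within the aortic ROI
#'
#' Pixels inside the aortic band whose intensity exceeds an adaptive
#' threshold — the median band intensity plus the larger of an absolute
#' floor and a multiple of the band's median absolute deviation — are marked
#' calcified; pixels at or above the saturation level are always marked.
#' Isolated small components are removed, and per-(level, wall) coverage is
#' measured by row projection: the fraction of the level's rows containing
#' at least one calcified pixel in that wall sub-band. Row projection (not
#' pixel area) matches the Kauppila convention of scoring calcification
#' *length* along the vertebra.
#'
#' @param image a [dexa_image].
#' @param roi an `aortic_roi` from [extract_aortic_roi()].
#' @param abs_floor minimum threshold elevation above the band median
#'   (0-1 intensity units).
#' @param mad_factor multiple of the band MAD used when noise dominates the
#'   floor.
#' @param min_size minimum connected-component size (pixels) kept; the default
#'   equals the pixel footprint of a single-row calcific streak.
#' @param saturation intensity at/above which a pixel is always calcified.
#' @return Object of class `calc_mask`: `mask` (logical matrix), `coverage`
#'   (named fractions over the 8 bands), `threshold`.
#' @export
detect_calcification <- function(image, roi, abs_floor = 0.12,
                                 mad_factor = 4, min_size = 3,
                                 saturation = 0.99) {
  stopifnot(inherits(image, "dexa_image"), inherits(roi, "aortic_roi"))
  px <- image$pixels
  masks <- roi_masks(roi, dim(px))
  roi_all <- Reduce(`|`, masks)
  vals <- px[roi_all]
  if (length(vals) == 0L)
    abort_aac("empty aortic ROI", "aac_validation_error")

  bg <- median(vals)
  thr <- bg + max(abs_floor, mad_factor * mad(vals))
  calc <- roi_all & (px > thr | px >= saturation)

  if (any(calc)) {
    lab <- EBImage::bwlabel(calc)
    areas <- tabulate(as.integer(lab))
    small <- which(areas < min_size)
    if (length(small)) calc[matrix(as.integer(lab), nrow(px)) %in% small] <- FALSE
  }

  structure(list(mask = calc, coverage = coverage_from_mask(calc, roi),
                 threshold = thr),
            class = "calc_mask")
}

#' Per-wall coverage fractions of a binary calcification mask
#'
#' Row-projected coverage: for each (level, wall) sub-band, the fraction of
#' the level's rows containing at least one calcified pixel inside that
#' wall's columns. Pixels of the mask outside the ROI are ignored.
#'
#' @param mask logical matrix, same grid as the image the ROI refers to.
#' @param roi an `aortic_roi`.
#' @return Named numeric vector of 8 coverage fractions.
#' @export
coverage_from_mask <- function(mask, roi) {
  masks <- roi_masks(roi, dim(mask))
  cov <- setNames(numeric(8L), wall_keys())
  for (i in seq_len(nrow(roi$levels))) {
    lev <- roi$levels$level[i]
    rows <- roi$levels$row_min[i]:roi$levels$row_max[i]
    h <- roi$levels$height[i]
    for (w in aac_walls) {
      key <- paste(lev, w, sep = "_")
      wm <- mask & masks[[key]]
      cov[key] <- sum(rowSums(wm[rows, , drop = FALSE]) > 0) / h
    }
  }
  cov
}

#' Per-wall Kauppila score from a coverage fraction
#'
#' Maps the projected calcification length, as a fraction `f` of the
#' vertebral height, to the semi-quantitative 0-3 wall score: 0 when `f` is
#' at or below the noise floor `eps`; 1 when the length is under one third
#' of the vertebra; 2 from one third to two thirds (both boundaries
#' included); 3 beyond two thirds.
#'
#' @param f coverage fraction(s) in 0-1 (vectorized).
#' @param eps noise floor below which a wall scores 0; visible calcification
#'   is reader-defined in manual scoring, so a small numeric floor (default
#'   2% of vertebral height) stands in for "visible".
#' @return Integer score(s) in 0-3.
#' @examples
#' score_wall(c(0, 0.2, 0.5, 0.8))
#' @export
score_wall <- function(f, eps = 0.02) {
  if (any(!is.finite(f)) || any(f < 0 | f > 1))
    abort_aac("coverage fraction must lie in [0, 1]", "aac_validation_error")
  ifelse(f <= eps, 0L,
         ifelse(f < 1 / 3, 1L,
                ifelse(f <= 2 / 3, 2L, 3L)))
}

#' Kauppila score from per-wall coverage fractions
#'
#' Scores all 8 (level, wall) bands with [score_wall()] and sums them into
#' the 0-24 total.
#'
#' @param x a `calc_mask` from [detect_calcification()] or a named numeric
#'   vector of 8 coverage fractions over `L1_anterior` ... `L4_posterior`.
#' @param eps noise floor passed to [score_wall()].
#' @return Object of class `kauppila_score`: `walls` (named integer vector
#'   of 8 per-wall scores) and `total`.
#' @examples
#' ks <- kauppila_score(setNames(rep(1, 8), c(
#'   "L1_anterior", "L2_anterior", "L3_anterior", "L4_anterior",
#'   "L1_posterior", "L2_posterior", "L3_posterior", "L4_posterior")))
#' ks$total  # 24
#' @export
kauppila_score <- function(x, eps = 0.02) {
  f <- if (inherits(x, "calc_mask")) x$coverage else x
  f <- unlist(f)
  if (!all(wall_keys() %in% names(f)))
    abort_aac(paste("missing wall coverage:",
                    paste(setdiff(wall_keys(), names(f)), collapse = ", ")),
              "aac_validation_error")
  f <- f[wall_keys()]
  walls <- setNames(score_wall(f, eps = eps), wall_keys())
  structure(list(walls = walls, total = as.integer(sum(walls))),
            class = "kauppila_score")
}

#' @export
print.kauppila_score <- function(x, ...) {
  cat("<kauppila_score> total =", x$total, "\n")
  m <- matrix(x$walls[wall_keys()], nrow = 2, byrow = TRUE,
              dimnames = list(aac_walls, aac_levels))
  print(m)
  invisible(x)
}

## per-band features shared by the regression scorer: coverage fraction plus
## intensity statistics of each wall sub-band
roi_features <- function(image, roi, ...) {
  det <- detect_calcification(image, roi, ...)
  px <- image$pixels
  masks <- roi_masks(roi, dim(px))
  bg <- median(px[Reduce(`|`, masks)])
  stats <- unlist(lapply(wall_keys(), function(k) {
    v <- px[masks[[k]]] - bg
    c(mean = mean(v), p90 = unname(quantile(v, 0.9)))
  }))
  c(det$coverage, setNames(stats, paste0(rep(wall_keys(), each = 2),
                                         c("_mean", "_p90"))))
}

#' Train the learned score regressor
#'
#' Fits a single-hidden-layer neural network regression from aortic-ROI
#' features (per-wall detected coverage plus band intensity statistics) to
#' the total AAC score, the learned analog of scoring by regression on the
#' localized region.
#'
#' @param images list of [dexa_image] objects.
#' @param scores numeric vector of reference total scores (0-24), e.g.
#'   annotation consensus or phantom ground truth.
#' @param size,decay,maxit network hyperparameters.
#' @param seed RNG seed for weight initialization.
#' @return An `aac_regressor` model handle for [regress_score()].
#' @export
train_score_regressor <- function(images, scores, size = 8, decay = 1e-2,
                                  maxit = 500, seed = 1L) {
  if (length(images) != length(scores))
    abort_aac("images and scores must have equal length",
              "aac_validation_error")
  feats <- vector("list", length(images))
  ok <- rep(TRUE, length(images))
  for (i in seq_along(images)) {
    f <- tryCatch({
      boxes <- detect_vertebrae(images[[i]])
      curve <- fit_spine_curve(boxes)
      roi <- extract_aortic_roi(curve, boxes,
                                image_dim = dim(images[[i]]$pixels))
      roi_features(images[[i]], roi)
    }, aac_error = function(e) NULL)
    if (is.null(f)) ok[i] <- FALSE else feats[[i]] <- f
  }
  if (sum(ok) < 10L)
    abort_aac("too few images survived localization for training",
              "aac_validation_error")
  x <- do.call(rbind, feats[ok])
  y <- scores[ok]
  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  fit <- local_seed(seed,
    nnet::nnet(xs, y / 24, size = size, decay = decay, maxit = maxit,
               linout = FALSE, trace = FALSE, MaxNWts = 5000))
  structure(list(fit = fit, center = ctr, scale = scl,
                 format_version = "1.0", n_train = sum(ok)),
            class = "aac_regressor")
}

#' Predict a continuous AAC score from an aortic ROI
#'
#' Deterministic at inference: the same model and input always give the same
#' prediction, clipped to the 0-24 score range.
#'
#' @param image a [dexa_image].
#' @param roi an `aortic_roi`.
#' @param model an `aac_regressor` from [train_score_regressor()].
#' @return A single numeric score in 0-24.
#' @export
regress_score <- function(image, roi, model) {
  if (is.null(model) || !inherits(model, "aac_regressor"))
    abort_aac("regress_score requires a trained aac_regressor",
              "aac_config_error")
  f <- roi_features(image, roi)
  xs <- scale(matrix(f, nrow = 1), center = model$center, scale = model$scale)
  pmin(pmax(as.numeric(predict(model$fit, xs)) * 24, 0), 24)
}

#' Ensemble of two pipeline scores
#'
#' Arithmetic mean of the two pipelines' total scores. If exactly one
#' pipeline failed (score `NA`), the other score is returned with attribute
#' `single_pipeline = TRUE`; if both failed a localization failure is
#' raised.
#'
#' @param s1,s2 total scores in 0-24, or `NA` for a failed pipeline.
#' @return Numeric ensemble score, possibly with attribute
#'   `single_pipeline`.
#' @examples
#' ensemble_score(4, 6)  # 5
#' @export
ensemble_score <- function(s1, s2) {
  ok1 <- length(s1) == 1L && is.finite(s1)
  ok2 <- length(s2) == 1L && is.finite(s2)
  if (!ok1 && !ok2)
    abort_aac("both pipelines failed", "aac_localization_error")
  for (s in c(s1, s2)[c(ok1, ok2)])
    if (s < 0 || s > 24)
      abort_aac("scores must lie in [0, 24]", "aac_validation_error")
  if (ok1 && ok2) return((s1 + s2) / 2)
  structure(if (ok1) s1 else s2, single_pipeline = TRUE)
}

#' Score one image end-to-end with both pipelines
#'
#' Pipeline 1 localizes the spine by classical segmentation; pipeline 2 by
#' per-vertebra box detection on the learned segmenter when a model is
#' supplied (falling back to the classical front-end otherwise). Both then
#' fit the spine curve, extract the aortic ROI and score it — rule-based by
#' default, or by learned regression when `reg_model` is given. The ensemble
#' averages the two pipelines' totals; a pipeline that fails localization is
#' skipped and flagged.
#'
#' @param image a [dexa_image].
#' @param seg_model optional `spine_seg_model` for pipeline 2's front-end.
#' @param reg_model optional `aac_regressor`; when supplied both pipelines
#'   score by regression, otherwise both use the rule-based scorer.
#' @param offset_factor,width_factor ROI geometry (see
#'   [extract_aortic_roi()]).
#' @param eps rule-based noise floor (see [score_wall()]).
#' @return One-row `data.frame`: image id, the 8 per-wall rule scores from
#'   pipeline 1, `total_p1`, `total_p2`, `ensemble`, failure flags and a
#'   `single_pipeline` flag.
#' @export
score_image <- function(image, seg_model = NULL, reg_model = NULL,
                        offset_factor = 1.2, width_factor = 0.8, eps = 0.02) {
  run_pipeline <- function(method, model) {
    boxes <- detect_vertebrae(image, method = method, model = model)
    curve <- fit_spine_curve(boxes)
    roi <- extract_aortic_roi(curve, boxes, offset_factor = offset_factor,
                              width_factor = width_factor,
                              image_dim = dim(image$pixels))
    if (is.null(reg_model)) {
      ks <- kauppila_score(detect_calcification(image, roi), eps = eps)
      list(total = ks$total, walls = ks$walls)
    } else {
      list(total = regress_score(image, roi, reg_model), walls = NULL)
    }
  }
  p1 <- tryCatch(run_pipeline("classical", NULL),
                 aac_error = function(e) NULL)
  p2 <- tryCatch(
    run_pipeline(if (is.null(seg_model)) "classical" else "learned",
                 seg_model),
    aac_error = function(e) NULL)

  s1 <- if (is.null(p1)) NA_real_ else p1$total
  s2 <- if (is.null(p2)) NA_real_ else p2$total
  ens <- tryCatch(ensemble_score(s1, s2), aac_error = function(e) NA_real_)

  walls <- if (!is.null(p1$walls)) p1$walls
           else setNames(rep(NA_integer_, 8L), wall_keys())
  out <- data.frame(id = image$id, t(walls),
                    total_p1 = s1, total_p2 = s2,
                    ensemble = as.numeric(ens),
                    p1_failed = is.null(p1), p2_failed = is.null(p2),
                    single_pipeline = isTRUE(attr(ens, "single_pipeline")))
  rownames(out) <- NULL
  out
}

#' Score a set of images
#'
#' Applies [score_image()] to each image; images failing both pipelines are
#' reported with `NA` scores rather than aborting the batch.
#'
#' @param images list of [dexa_image] objects (or phantom records with an
#'   `$image` element).
#' @param ... forwarded to [score_image()].
#' @return A `data.frame` with one row per image.
#' @export
score_image_set <- function(images, ...) {
  rows <- lapply(images, function(im) {
    if (!inherits(im, "dexa_image") && !is.null(im$image)) im <- im$image
    score_image(im, ...)
  })
  do.call(rbind, rows)
}

#' Write a score table as TSV
#'
#' @param scores data.frame from [score_image_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
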