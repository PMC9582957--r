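#' Median consensus of annotator scores
#'
#' The consensus for an image is the median across annotators; with an even
#' number of annotators it is the mean of the two middle values (possibly
#' non-integer). The median bounds the influence of any single outlying
#' annotator.
#'
#' @param scores numeric vector of per-annotator total scores for one image.
#' @return The consensus value.
#' @examples
#' consensus_score(c(3, 5, 5, 20))  # 5
#' @export
consensus_score <- function(scores) {
  if (length(scores) == 0L)
    abort_aac("at least one annotation is required", "aac_validation_error")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 24))
    abort_aac("annotation scores must lie in [0, 24]", "aac_validation_error")
  median(scores)
}

#' Split image ids into a train/test set and a held-out validation set
#'
#' Seeded, reproducible, disjoint split; mirrors the workflow of scoring a
#' large annotated pool, developing on one part and validating on the
#' held-out remainder.
#'
#' @param ids vector of image ids (or an annotation `data.frame` with an
#'   `image_id` column, whose unique ids are split).
#' @param sizes `c(train_test, validation)` set sizes; must sum to at most
#'   the number of ids.
#' @param seed RNG seed.
#' @return List with `train_test` and `validation` id vectors.
#' @export
split_dataset <- function(ids, sizes = c(1000L, 300L), seed = 1L) {
  if (is.data.frame(ids)) ids <- unique(ids$image_id)
  ids <- unique(ids)
  if (sum(sizes) > length(ids))
    abort_aac(sprintf("requested %d ids from a pool of %d",
                      sum(sizes), length(ids)), "aac_validation_error")
  local_seed(seed, {
    perm <- sample(ids)
    list(train_test = perm[seq_len(sizes[1])],
         validation = perm[sizes[1] + seq_len(sizes[2])])
  })
}

#' Agreement metrics between predicted and reference scores
#'
#' Mean absolute error and Pearson product-moment correlation of paired
#' score vectors; `r` is reported as `NA` (with a note) when the reference
#' is constant.
#'
#' @param predicted,reference paired numeric vectors (length >= 2).
#' @param per_annotator optional annotation `data.frame` (`image_id`,
#'   `annotator_id`, `score`): when given, per-annotator MAE against the
#'   median consensus is included.
#' @return Object of class `agreement_report`: `mae`, `pearson_r`, `n`, and
#'   optionally `per_annotator_mae`.
#' @examples
#' agreement_stats(c(0, 2, 4), c(1, 3, 5))  # MAE 1, r 1
#' @export
agreement_stats <- function(predicted, reference, per_annotator = NULL) {
  if (length(predicted) != length(reference))
    abort_aac("predicted and reference must have equal length",
              "aac_validation_error")
  if (length(predicted) < 2L)
    abort_aac("at least two pairs are required", "aac_validation_error")
  mae <- mean(abs(predicted - reference))
  r <- if (sd(reference) == 0 || sd(predicted) == 0) {
    message("constant vector: Pearson correlation undefined")
    NA_real_
  } else cor(predicted, reference)
  rep_ <- list(mae = mae, pearson_r = r, n = length(predicted))
  if (!is.null(per_annotator)) {
    cons <- tapply(per_annotator$score, per_annotator$image_id, median)
    rep_$per_annotator_mae <- sapply(
      split(per_annotator, per_annotator$annotator_id),
      function(d) mean(abs(d$score - cons[as.character(d$image_id)])))
  }
  structure(rep_, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d, MAE = %.3f, Pearson r = %s\n",
              x$n, x$mae,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r)))
  if (!is.null(x$per_annotator_mae)) {
    cat("per-annotator MAE vs consensus:\n")
    print(round(x$per_annotator_mae, 3))
  }
  invisible(x)
}

#' Read and write annotation tables
#'
#' Annotations are TSV with columns `image_id`, `annotator_id`, `score`.
#'
#' @param annotations `data.frame` with those three columns.
#' @param path TSV path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   the `data.frame`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("image_id", "annotator_id", "score") %in%
                  names(annotations)))
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  ann <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("image_id", "annotator_id", "score") %in% names(ann)))
    abort_aac("annotation TSV needs image_id, annotator_id, score columns",
              "aac_validation_error")
  if (any(ann$score < 0 | ann$score > 24))
    abort_aac("annotation scores must lie in [0, 24]", "aac_validation_error")
  ann
}
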