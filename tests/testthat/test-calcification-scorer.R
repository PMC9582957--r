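test_that("per-wall scoring thresholds at one and two thirds of the vertebra", {
  expect_identical(score_wall(c(0, 0.2, 0.5, 0.8)), c(0L, 1L, 2L, 3L))
  # both boundaries belong to score 2 ("from 1/3 to 2/3")
  expect_identical(score_wall(c(1 / 3, 2 / 3)), c(2L, 2L))
  expect_identical(score_wall(c(0.015, 0.021)), c(0L, 1L))  # noise floor
  expect_identical(score_wall(1), 3L)
  expect_error(score_wall(1.2), class = "aac_validation_error")
  expect_error(score_wall(-0.1), class = "aac_validation_error")
  # monotone non-decreasing in coverage
  f <- sort(runif(200))
  expect_true(all(diff(score_wall(f)) >= 0))
})

test_that("total score sums the eight wall scores", {
  expect_identical(kauppila_score(cov8(ant = rep(1, 4), post = rep(1, 4)))$total,
                   24L)
  expect_identical(kauppila_score(cov8())$total, 0L)
  ks <- kauppila_score(cov8(ant = c(0.2, 0.5, 0.8, 0)))
  expect_identical(ks$total, 6L)
  expect_identical(ks$total, as.integer(sum(ks$walls)))
  expect_error(kauppila_score(cov8()[-1]), class = "aac_validation_error")
})

test_that("row-projected scoring equals the brute-force per-pixel oracle", {
  ph <- generate_phantom(clean_config(seed = 55))
  boxes <- detect_vertebrae(ph$image)
  roi <- extract_aortic_roi(fit_spine_curve(boxes), boxes,
                            image_dim = dim(ph$image$pixels))
  set.seed(99)
  for (i in 1:200) {
    m <- random_roi_mask(roi, dim(ph$image$pixels),
                         p = runif(1, 0.01, 0.5))
    expect_identical(kauppila_score(coverage_from_mask(m, roi))$total,
                     oracle_kauppila(m, roi))
  }
})

test_that("detected coverage matches the rendered deposit extent", {
  ph <- generate_phantom(clean_config(coverage = cov8(ant = c(0, 0, 0.5, 0)),
                                      seed = 6))
  boxes <- detect_vertebrae(ph$image)
  roi <- extract_aortic_roi(fit_spine_curve(boxes), boxes,
                            image_dim = dim(ph$image$pixels))
  det <- detect_calcification(ph$image, roi)
  # exact agreement with the realized (pixel-quantized) truth, and within
  # one row of the requested half-height extent
  expect_equal(det$coverage[["L3_anterior"]],
               ph$truth$coverage[["L3_anterior"]])
  h3 <- ph$truth$vertebrae$height[3]
  expect_lte(abs(det$coverage[["L3_anterior"]] - 0.5), 1 / h3)
  expect_equal(sum(det$coverage > 0), 1)

  ph0 <- generate_phantom(clean_config(coverage = cov8(), seed = 7))
  det0 <- detect_calcification(ph0$image, roi)
  expect_true(all(det0$coverage == 0))

  # uniformly saturated aortic band -> full coverage everywhere
  px <- ph0$image$pixels
  px[Reduce(`|`, roi_masks(roi, dim(px)))] <- 1
  det1 <- detect_calcification(dexa_image(px, id = "saturated"), roi)
  expect_true(all(det1$coverage == 1))
})

test_that("learned regression tracks ground truth and is deterministic", {
  train <- generate_image_set(80, phantom_config(), seed = 800)
  model <- train_score_regressor(lapply(train, `[[`, "image"),
                                 vapply(train, function(p)
                                   p$truth$true_score$total, integer(1)),
                                 seed = 3)
  val <- generate_image_set(30, phantom_config(), seed = 900)
  truth <- vapply(val, function(p) p$truth$true_score$total, integer(1))
  pred <- vapply(val, function(p) {
    boxes <- detect_vertebrae(p$image)
    roi <- extract_aortic_roi(fit_spine_curve(boxes), boxes,
                              image_dim = dim(p$image$pixels))
    regress_score(p$image, roi, model)
  }, numeric(1))
  expect_gte(cor(pred, truth), 0.67)
  expect_true(all(pred >= 0 & pred <= 24))

  # deterministic at inference; near zero on a blank aorta
  blank <- generate_phantom(clean_config(coverage = cov8(), seed = 1))
  boxes <- detect_vertebrae(blank$image)
  roi <- extract_aortic_roi(fit_spine_curve(boxes), boxes,
                            image_dim = dim(blank$image$pixels))
  p1 <- regress_score(blank$image, roi, model)
  expect_identical(p1, regress_score(blank$image, roi, model))
  expect_lt(p1, 1)
  expect_error(regress_score(blank$image, roi, NULL),
               class = "aac_config_error")
})

test_that("ensemble averages, falls back on single failures, stays bounded", {
  expect_equal(ensemble_score(4, 6), 5)
  expect_equal(ensemble_score(17.5, 17.5), 17.5)
  e <- ensemble_score(3, NA)
  expect_equal(as.numeric(e), 3)
  expect_true(attr(e, "single_pipeline"))
  expect_error(ensemble_score(NA, NA), class = "aac_localization_error")
  expect_error(ensemble_score(25, 3), class = "aac_validation_error")
  set.seed(2)
  for (i in 1:50) {
    s <- runif(2, 0, 24)
    e <- ensemble_score(s[1], s[2])
    expect_gte(e, min(s)); expect_lte(e, max(s))
  }
})

test_that("batch scoring reports failures instead of aborting", {
  good <- generate_phantom(clean_config(seed = 10))
  blank <- dexa_image(matrix(0.05, 160, 96), id = "blank")
  res <- score_image_set(list(good, blank))
  expect_equal(nrow(res), 2)
  expect_false(res$p1_failed[1])
  expect_true(res$p1_failed[2] && res$p2_failed[2])
  expect_true(is.na(res$ensemble[2]))
  expect_equal(res$total_p1[1], good$truth$true_score$total)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(res, path)
  back <- read.table(path, sep = "\t", header = TRUE)
  expect_equal(back$ensemble[1], res$ensemble[1])
})
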