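test_that("phantom ground-truth scores follow the Kauppila rule on coverage", {
  ph0 <- generate_phantom(clean_config(coverage = cov8()))
  expect_identical(ph0$truth$true_score$total, 0L)

  ph24 <- generate_phantom(clean_config(coverage = cov8(ant = rep(1, 4),
                                                        post = rep(1, 4))))
  expect_identical(ph24$truth$true_score$total, 24L)

  ph6 <- generate_phantom(clean_config(coverage = cov8(ant = c(0.2, 0.5, 0.8, 0))))
  expect_identical(unname(ph6$truth$true_score$walls[
    c("L1_anterior", "L2_anterior", "L3_anterior", "L4_anterior")]),
    c(1L, 2L, 3L, 0L))
  expect_identical(ph6$truth$true_score$total, 6L)
})

test_that("phantom generation is bit-identical for a fixed config and seed", {
  cfg <- phantom_config(seed = 77L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$coverage, b$truth$coverage)

  set1 <- generate_image_set(10, phantom_config(), seed = 5)
  set2 <- generate_image_set(10, phantom_config(), seed = 5)
  expect_identical(lapply(set1, function(p) digest_sum(p$image$pixels)),
                   lapply(set2, function(p) digest_sum(p$image$pixels)))
  expect_identical(generate_image_set(0), list())
})

test_that("requested coverage is realized within one pixel of vertebral height", {
  set.seed(31)
  for (rep in 1:10) {
    f_req <- cov8(ant = runif(4), post = runif(4))
    ph <- generate_phantom(clean_config(coverage = f_req, seed = 100 + rep))
    tr <- ph$truth
    for (i in 1:4) {
      b <- tr$vertebrae[i, ]
      mid <- tr$curve_coef[1] + tr$curve_coef[2] * (b$row_min:b$row_max) +
        tr$curve_coef[3] * (b$row_min:b$row_max)^2 + tr$offset_px
      for (w in c("anterior", "posterior")) {
        key <- paste(b$level, w, sep = "_")
        sub <- tr$calc_mask[b$row_min:b$row_max, , drop = FALSE]
        n_rows <- sum(vapply(seq_len(nrow(sub)), function(j) {
          cols <- which(sub[j, ])
          if (w == "anterior") any(cols >= mid[j]) else any(cols < mid[j])
        }, logical(1)))
        expect_lte(abs(n_rows - f_req[[key]] * b$height), 1)
        expect_equal(n_rows / b$height, tr$coverage[[key]])
      }
    }
  }
})

test_that("default coverage sampling is skewed toward low scores", {
  set3 <- generate_image_set(300, phantom_config(), seed = 1234)
  totals <- vapply(set3, function(p) p$truth$true_score$total, integer(1))
  expect_gt(mean(totals < 3), 0.5)
  expect_gt(mean(totals == 0), 0.2)
})

test_that("phantom config validation rejects bad coverage and tiny grids", {
  expect_error(phantom_config(coverage = cov8(ant = c(1.2, 0, 0, 0))),
               class = "aac_validation_error")
  expect_error(phantom_config(rows = 100), class = "aac_config_error")
  expect_error(phantom_config(rows = 40, cols = 20), class = "aac_config_error")
})

test_that("cohort marginal matches the prevalence regime and statin target", {
  co <- generate_cohort(20000, seed = 42)
  expect_gt(mean(co$aac_score), 1.3)
  expect_lt(mean(co$aac_score), 1.6)
  expect_gt(mean(co$aac_score > 3), 0.10)
  expect_lt(mean(co$aac_score > 3), 0.13)
  expect_equal(mean(co$statin_user), 0.15, tolerance = 0.015)
  expect_true(all(co$aac_score >= 0 & co$aac_score <= 24))
  # statin users carry higher *untreated* LDL (confounding by indication)
  expect_gt(mean(co$ldl_untreated[co$statin_user]),
            mean(co$ldl_untreated[!co$statin_user]))
  expect_identical(co, generate_cohort(20000, seed = 42))
})

test_that("cohort covariate effects on AAC are recovered by regression", {
  co <- generate_cohort(100000, seed = 9)
  fit <- lm(aac_score ~ I(smoking == "previous") + I(smoking == "current") +
              scale(age_imaging) + sex, data = co)
  sm <- summary(fit)$coefficients
  for (term in rownames(sm)[2:4]) {
    est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
    expect_gt(0.12, est - 2.5 * se)
    expect_lt(0.12, est + 2.5 * se)
  }
})

test_that("additive statin masking is exactly inverted by model-1 adjustment", {
  pars <- cohort_params(statin_effect = list(type = "additive",
                                             ldl = 1.25, trig = 1.25))
  co <- generate_cohort(3000, pars, seed = 11)
  adj <- adjust_ldl_statin(co$ldl, co$triglycerides, co$statin_user, model = 1)
  expect_equal(adj$ldl_adjusted, co$ldl_untreated, tolerance = 1e-12)

  # proportional masking is exactly inverted by model 2
  co2 <- generate_cohort(3000, cohort_params(), seed = 12)
  adj2 <- adjust_ldl_statin(co2$ldl, co2$triglycerides, co2$statin_user,
                            model = 2)
  expect_equal(adj2$ldl_adjusted, co2$ldl_untreated, tolerance = 1e-12)
})

test_that("null AAC hazard yields approximately nominal rejection", {
  reject <- logical(60)
  for (r in seq_len(60)) {
    pars <- cohort_params(diseases = list(
      d = list(hr_aac = 1.0, base_rate = 0.02, horizon = 3,
               prior_prob = 0)))
    co <- generate_cohort(1500, pars, seed = 2000 + r)
    scr <- prognosis_screen(co, "d", model = 1)
    reject[r] <- nrow(scr) == 1 && scr$p < 0.05
  }
  expect_lte(mean(reject), 0.15)  # binomial slack around alpha = 0.05
})

test_that("cohort parameter validation rejects bad inputs", {
  expect_error(generate_cohort(0), class = "aac_validation_error")
  expect_error(cohort_params(diseases = list(d = list(hr_aac = -1))),
               class = "aac_validation_error")
})

test_that("phantom images and cohorts round-trip through disk formats", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(clean_config(coverage = cov8(ant = c(0, 0.5, 0, 0))))
  path <- write_phantom(ph, dir)
  back <- read_dexa(path)
  expect_lt(max(abs(back$pixels - pmin(pmax(ph$image$pixels, 0), 1))),
            1.5 / 65535)  # 16-bit quantization
  sidecar <- jsonlite::read_json(file.path(dir, paste0(ph$image$id,
                                                       ".truth.json")))
  expect_equal(sidecar$true_score$total, 2)

  co <- generate_cohort(50, seed = 3)
  p <- file.path(dir, "cohort.csv")
  write_cohort(co, p)
  expect_equal(read_cohort(p)$aac_score, co$aac_score, tolerance = 1e-9)
})
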