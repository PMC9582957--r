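test_that("prevalence summary reports moments, threshold and tail fraction", {
  pv <- prevalence_summary(c(1, 3))
  expect_equal(pv$mean, 2)
  expect_equal(pv$sd, sd(c(1, 3)))         # sample sd, n - 1
  expect_equal(pv$threshold, 2 + sqrt(2))
  expect_equal(pv$frac_gt3, 0)

  pv0 <- prevalence_summary(rep(0, 10))
  expect_equal(pv0$mean, 0)
  expect_equal(pv0$frac_gt3, 0)
  expect_error(prevalence_summary(1), class = "aac_validation_error")

  co <- generate_cohort(5000, seed = 21)
  pvs <- prevalence_summary(co$aac_score, co$age_imaging, co$sex)
  expect_true(all(c("decade", "sex", "n") %in% names(pvs$by_stratum)))
  expect_equal(sum(pvs$by_stratum$n), nrow(co))
  # age-dependent increase: oldest decade has higher median score
  med <- with(pvs$by_stratum, tapply(`50%`, decade, mean))
  expect_gt(med[length(med)], med[1])
})

test_that("statin adjustment models follow the stated arithmetic", {
  # non-users unchanged under every model
  co <- generate_cohort(500, seed = 2)
  imp <- fit_lipid_imputer(co)
  for (m in 1:3) {
    adj <- adjust_ldl_statin(co$ldl, co$triglycerides, co$statin_user,
                             model = m, imputer = imp, data = co)
    non <- !co$statin_user
    expect_equal(adj$ldl_adjusted[non], co$ldl[non])
    expect_equal(adj$trig_adjusted[non], co$triglycerides[non])
  }
  # model 1: additive increment
  expect_equal(adjust_ldl_statin(3.0, 1.0, TRUE, model = 1)$ldl_adjusted, 4.25)
  # model 2: inverse of a 35% reduction = x1/0.65, a ~54% relative increase
  expect_equal(adjust_ldl_statin(2.0, 1.0, TRUE, model = 2)$ldl_adjusted,
               2 / 0.65, tolerance = 1e-12)
  expect_equal(round(adjust_ldl_statin(2.0, 1.0, TRUE, model = 2)$ldl_adjusted,
                     2), 3.08)
  # model 3: imputed values correlate with the untreated truth far better
  # than the statin-masked measurements do
  adj3 <- adjust_ldl_statin(co$ldl, co$triglycerides, co$statin_user,
                            model = 3, imputer = imp, data = co)
  users <- co$statin_user
  if (sum(users) > 10) {
    expect_lt(mean(abs(adj3$ldl_adjusted[users] - co$ldl_untreated[users])),
              mean(abs(co$ldl[users] - co$ldl_untreated[users])))
  }
  expect_error(adjust_ldl_statin(3, 1, TRUE, model = 4),
               class = "aac_validation_error")
  expect_error(adjust_ldl_statin(3, 1, TRUE, model = 3),
               class = "aac_config_error")
  expect_error(adjust_ldl_statin(-1, 1, TRUE, model = 1),
               class = "aac_validation_error")
})

test_that("cystatin-C eGFR evaluates the 2012 equation and is monotone", {
  ref <- egfr_cystatin(0.8, 50, "female")
  expect_equal(ref, 133 * 0.996^50 * 0.932, tolerance = 1e-12)
  expect_gt(ref, 90); expect_lt(ref, 110)   # normal kidney function
  expect_lt(egfr_cystatin(1.6, 50, "female"), ref)
  cys <- seq(0.4, 3, by = 0.1)
  expect_true(all(diff(egfr_cystatin(cys, 60, "male")) < 0))
  expect_error(egfr_cystatin(0, 50, "female"), class = "aac_validation_error")
})

test_that("biomarker associations recover the simulated structure", {
  co <- generate_cohort(10000, seed = 17)
  # a biomarker identical to AAC: effect per SD equals sd(AAC), perfect fit
  co$self <- co$aac_score
  a <- suppressWarnings(biomarker_association(co, "self", model = 1))
  expect_equal(a$effect_per_sd, sd(co$aac_score), tolerance = 1e-6)

  # HbA1c simulated positively correlated with AAC; LDL simulated null
  hb <- biomarker_association(co, "hba1c", model = 1, n_tests = 416)
  expect_gt(hb$effect_per_sd, 0)
  expect_true(hb$significant)
  ld <- biomarker_association(co, "ldl", model = 1, n_tests = 416)
  expect_false(ld$significant)
  expect_lt(abs(ld$effect_per_sd), 0.1)
  expect_equal(hb$bonferroni_threshold, 0.05 / 416)

  # model 2 carries the confounder set
  hb2 <- biomarker_association(co, "hba1c", model = 2)
  expect_equal(hb2$model, "model2")

  expect_error(biomarker_association(co, "nope"),
               class = "aac_validation_error")
  co$flat <- 1
  expect_error(biomarker_association(co, "flat"),
               class = "aac_validation_error")
})

test_that("null biomarkers stay below the Bonferroni threshold", {
  hits <- vapply(1:20, function(r) {
    co <- generate_cohort(2000, seed = 300 + r)
    biomarker_association(co, "ldl", model = 1, n_tests = 416)$significant
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("prognosis screen filters, excludes prior history, corrects p-values", {
  pars <- cohort_params(diseases = list(
    common = list(hr_aac = 1.4, base_rate = 0.02, horizon = 3,
                  prior_prob = 0.05),
    rare = list(hr_aac = 1.4, base_rate = 0.0002, horizon = 3,
                prior_prob = 0.05)))
  co <- generate_cohort(5000, pars, seed = 31)
  scr <- prognosis_screen(co, c("common", "rare"), model = 1)
  expect_identical(scr$disease, "common")          # rare fails the >25 filter
  expect_equal(scr$n, sum(co$common_prior == 0))   # brute-force prior filter
  expect_true(scr$ci_lo <= 1.4 && scr$ci_hi >= 1.4)
  expect_equal(scr$p_bonferroni, pmin(1, scr$p * nrow(scr)))

  expect_warning(prognosis_screen(co, "rare", model = 1), "event filter")
  expect_error(prognosis_screen(co, "common", min_events = 0),
               class = "aac_validation_error")
  expect_error(prognosis_screen(co, "missing"), class = "aac_validation_error")

  # model 2 runs with the extended covariate set
  scr2 <- prognosis_screen(co, "common", model = 2)
  expect_equal(nrow(scr2), 1)
})

test_that("Bonferroni keeps the adjusted set inside the raw set", {
  pars <- cohort_params(diseases = setNames(
    rep(list(list(hr_aac = 1.2, base_rate = 0.015, horizon = 3,
                  prior_prob = 0.02)), 6), paste0("d", 1:6)))
  co <- generate_cohort(4000, pars, seed = 8)
  scr <- prognosis_screen(co, paste0("d", 1:6), model = 1)
  expect_true(all(scr$p_bonferroni >= scr$p))
  expect_true(all(scr$disease[scr$significant] %in% scr$disease[scr$p < 0.05]))
})

test_that("joint MI model recovers independent AAC and LDL hazards", {
  co <- generate_cohort(8000, seed = 5)
  jm <- joint_mi_model(co, statin_model = 2)
  est <- jm$estimates
  aac <- est[est$term == "aac", ]
  ldl <- est[est$term == "ldl", ]
  expect_true(aac$ci_lo <= 1.4 && aac$ci_hi >= 1.4)
  expect_true(ldl$ci_lo <= 1.4 && ldl$ci_hi >= 1.4)
  expect_gt(jm$interaction_p, 0.05)

  # statin adjustment deconfounds: adjusted-LDL HR closer to truth than raw
  jm0 <- joint_mi_model(co, statin_model = 0)
  raw_ldl <- jm0$estimates[jm0$estimates$term == "ldl", "hr_per_sd"]
  adj_ldl <- ldl$hr_per_sd
  expect_lt(abs(log(adj_ldl) - log(1.4)), abs(log(raw_ldl) - log(1.4)))

  # non-user subgroup still shows the AAC hazard
  jmn <- joint_mi_model(co, statin_model = 1, subset = "nonusers")
  aacn <- jmn$estimates[jmn$estimates$term == "aac", ]
  expect_true(aacn$ci_lo <= 1.4 && aacn$ci_hi >= 1.4)
  expect_lt(jmn$n, jm$n)
})

test_that("null-effect simulation yields hazard ratios near one", {
  pars <- cohort_params(diseases = list(
    mi = list(hr_aac = 1, hr_ldl = 1, hr_trig = 1, hr_age = 1, hr_sex = 1,
              base_rate = 0.01, horizon = 12, prior_prob = 0.02)))
  co <- generate_cohort(6000, pars, seed = 13)
  jm <- joint_mi_model(co, statin_model = 2)
  for (i in seq_len(nrow(jm$estimates))) {
    expect_true(jm$estimates$ci_lo[i] <= 1 && jm$estimates$ci_hi[i] >= 1)
  }
})
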