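#' Prevalence summary of AAC scores
#'
#' Moments of the score distribution, the mean-plus-one-SD threshold, the
#' fraction of the population above score 3 (the long tail of clinically
#' significant calcification), and per-(age decade x sex) score quantiles
#' when ages and sexes are supplied.
#'
#' @param scores numeric AAC scores (n >= 2).
#' @param ages,sexes optional vectors parallel to `scores` for the
#'   stratified quantiles.
#' @return Object of class `prevalence_summary`: `mean`, `sd` (sample,
#'   n-1), `threshold = mean + sd`, `frac_gt3`, `n`, and `by_stratum`.
#' @export
prevalence_summary <- function(scores, ages = NULL, sexes = NULL) {
  if (length(scores) < 2L)
    abort_aac("at least two scores are required", "aac_validation_error")
  out <- list(mean = mean(scores), sd = sd(scores), n = length(scores))
  out$threshold <- out$mean + out$sd
  out$frac_gt3 <- mean(scores > 3)
  if (!is.null(ages) && !is.null(sexes)) {
    decade <- 10 * floor(ages / 10)
    strat <- expand.grid(decade = sort(unique(decade)),
                         sex = sort(unique(sexes)),
                         stringsAsFactors = FALSE)
    qs <- t(mapply(function(d, s) {
      x <- scores[decade == d & sexes == s]
      c(n = length(x),
        if (length(x)) quantile(x, c(0.25, 0.5, 0.75))
        else c(`25%` = NA, `50%` = NA, `75%` = NA))
    }, strat$decade, strat$sex))
    out$by_stratum <- cbind(strat, as.data.frame(qs))
  }
  structure(out, class = "prevalence_summary")
}

#' @export
print.prevalence_summary <- function(x, ...) {
  cat(sprintf(
    "<prevalence_summary> n = %d, mean = %.2f, sd = %.2f, mean+1sd = %.2f, P(score > 3) = %.1f%%\n",
    x$n, x$mean, x$sd, x$threshold, 100 * x$frac_gt3))
  invisible(x)
}

#' Reconstruct untreated lipid levels in statin users
#'
#' Statins lower measured LDL (and triglycerides); three adjustment models
#' reconstruct the untreated levels of users, always leaving non-users'
#' measured values unchanged. Model 1 adds a fixed increment (default 1.25
#' mmol/L) to both lipids. Model 2 assumes treatment reduced lipids by a
#' fixed fraction (default 35%) and inverts it, i.e. multiplies by
#' `1/(1 - reduction)` — a relative increase of ~54%. Model 3 imputes
#' untreated levels from blood pressure, pulse, age, sex and the non-lipid
#' biomarkers via a regression fitted on non-users ([fit_lipid_imputer()]).
#'
#' @param ldl,trig measured lipid levels (mmol/L), non-negative.
#' @param statin logical vector of statin use.
#' @param model 1, 2 or 3.
#' @param imputer a `lipid_imputer` (model 3 only).
#' @param data covariate `data.frame` for the imputer (model 3 only).
#' @param increment model-1 additive increment in mmol/L.
#' @param reduction model-2 assumed fractional reduction under treatment;
#'   the multiplicative increase is derived from it.
#' @return `data.frame` with columns `ldl_adjusted`, `trig_adjusted`.
#' @examples
#' adjust_ldl_statin(3.0, 1.0, statin = TRUE, model = 1)$ldl_adjusted  # 4.25
#' @export
adjust_ldl_statin <- function(ldl, trig, statin, model = 1, imputer = NULL,
                              data = NULL, increment = 1.25,
                              reduction = 0.35) {
  if (any(ldl < 0, na.rm = TRUE) || any(trig < 0, na.rm = TRUE))
    abort_aac("lipid levels must be non-negative", "aac_validation_error")
  if (!model %in% 1:3)
    abort_aac("model must be 1, 2 or 3", "aac_validation_error")
  statin <- as.logical(statin)
  ldl_adj <- ldl; trig_adj <- trig
  if (model == 1) {
    ldl_adj[statin] <- ldl[statin] + increment
    trig_adj[statin] <- trig[statin] + increment
  } else if (model == 2) {
    mult <- 1 / (1 - reduction)
    ldl_adj[statin] <- ldl[statin] * mult
    trig_adj[statin] <- trig[statin] * mult
  } else {
    if (is.null(imputer) || !inherits(imputer, "lipid_imputer"))
      abort_aac("model 3 requires a fitted lipid_imputer",
                "aac_config_error")
    if (is.null(data))
      abort_aac("model 3 requires the covariate data of the participants",
                "aac_validation_error")
    ldl_adj[statin] <- predict(imputer$ldl_fit, data[statin, , drop = FALSE])
    trig_adj[statin] <- pmax(
      predict(imputer$trig_fit, data[statin, , drop = FALSE]), 0.05)
  }
  data.frame(ldl_adjusted = ldl_adj, trig_adjusted = trig_adj)
}

#' Fit the model-3 lipid imputer on non-users
#'
#' Linear regressions of measured LDL and triglycerides on blood pressure,
#' pulse, age, sex and the non-lipid molecular biomarkers, fitted on
#' non-statin-users (whose measured levels are untreated).
#'
#' @param cohort cohort `data.frame` (see [generate_cohort()] for the
#'   expected columns).
#' @return Object of class `lipid_imputer` with `ldl_fit` and `trig_fit`.
#' @export
fit_lipid_imputer <- function(cohort) {
  nonusers <- cohort[!cohort$statin_user, ]
  rhs <- "sbp + dbp + pulse + age_baseline + sex + glucose + hba1c +
          phosphate + calcium + creatinine + cystatin_c"
  structure(list(
    ldl_fit = lm(as.formula(paste("ldl ~", rhs)), data = nonusers),
    trig_fit = lm(as.formula(paste("triglycerides ~", rhs)),
                  data = nonusers)),
    class = "lipid_imputer")
}

#' eGFR from serum cystatin C
#'
#' The 2012 CKD-EPI cystatin-C-only estimating equation:
#' `eGFR = 133 * min(Scys/0.8, 1)^-0.499 * max(Scys/0.8, 1)^-1.328 *
#' 0.996^age * 0.932^(female)`, in mL/min/1.73 m2. Strictly decreasing in
#' cystatin C.
#'
#' @param cystatin_c serum cystatin C in mg/L (> 0).
#' @param age age in years.
#' @param sex `"female"`/`"male"` (or logical `female`).
#' @return eGFR in mL/min/1.73 m2.
#' @export
egfr_cystatin <- function(cystatin_c, age, sex) {
  if (any(cystatin_c <= 0))
    abort_aac("cystatin C must be positive", "aac_validation_error")
  female <- if (is.logical(sex)) sex else sex == "female"
  r <- cystatin_c / 0.8
  133 * pmin(r, 1)^-0.499 * pmax(r, 1)^-1.328 * 0.996^age *
    ifelse(female, 0.932, 1)
}

## covariate right-hand sides of the two adjustment models used throughout
model_covariates <- function(model, age_col = "age_imaging") {
  if (model == 1) paste(age_col, "+ sex")
  else paste(age_col, "+ sex + bmi + ses + ethnicity + smoking")
}

#' Linear association of a biomarker with AAC
#'
#' Models AAC as a linear function of the standardized biomarker, adjusted
#' for age and sex (model 1) or additionally for BMI, socioeconomic index,
#' ethnicity and smoking (model 2). The reported effect is score units per
#' SD of the biomarker; Bonferroni significance is evaluated against
#' `alpha / n_tests`.
#'
#' @param cohort cohort `data.frame` with an `aac_score` column.
#' @param biomarker name of the biomarker column (must have variance).
#' @param model 1 or 2.
#' @param n_tests number of tests in the screening family (for the
#'   Bonferroni threshold).
#' @param alpha family-wise error target.
#' @return One-row `data.frame` of class `association_estimate`: effect per
#'   SD, 95% CI, p, Bonferroni threshold and significance flag, model tag.
#' @export
biomarker_association <- function(cohort, biomarker, model = 1,
                                  n_tests = 1, alpha = 0.05) {
  if (!biomarker %in% names(cohort))
    abort_aac(sprintf("biomarker '%s' not in cohort", biomarker),
              "aac_validation_error")
  x <- cohort[[biomarker]]
  if (sd(x, na.rm = TRUE) == 0)
    abort_aac("biomarker has no variance", "aac_validation_error")
  dat <- cohort
  dat$.bm <- as.numeric(scale(x))
  fm <- as.formula(paste("aac_score ~ .bm +", model_covariates(model)))
  fit <- lm(fm, data = dat)
  sm <- summary(fit)$coefficients[".bm", ]
  thr <- alpha / n_tests
  out <- data.frame(covariate = biomarker,
                    effect_per_sd = sm[["Estimate"]],
                    ci_lo = sm[["Estimate"]] - 1.96 * sm[["Std. Error"]],
                    ci_hi = sm[["Estimate"]] + 1.96 * sm[["Std. Error"]],
                    p = sm[["Pr(>|t|)"]],
                    bonferroni_threshold = thr,
                    significant = sm[["Pr(>|t|)"]] < thr,
                    model = paste0("model", model))
  class(out) <- c("association_estimate", "data.frame")
  out
}

#' Phenome-wide Cox proportional-hazards prognosis screen
#'
#' For each disease: participants with prior history are excluded; diseases
#' with no more than `min_events` events are dropped; the hazard of the
#' standardized AAC score is estimated with a Cox model (Efron ties) under
#' model-1 (age + sex) or model-2 covariates; two-tailed p-values are
#' Bonferroni-corrected across the tested diseases and significance called
#' at adjusted p < 0.05.
#'
#' @param cohort cohort `data.frame` with `<disease>_event`,
#'   `<disease>_time`, `<disease>_prior` columns.
#' @param diseases character vector of disease names.
#' @param model 1 or 2.
#' @param min_events diseases must have strictly more events than this
#'   (default 25) to be tested.
#' @param age_col age covariate column (default the imaging-visit age,
#'   matching an imaging-visit index date).
#' @return `data.frame` of class `hazard_screen`, one row per tested
#'   disease: HR per SD of AAC, 95% CI, p, Bonferroni-adjusted p,
#'   significance, events and n. Empty (with a warning) if nothing passes
#'   the event filter.
#' @export
prognosis_screen <- function(cohort, diseases, model = 1, min_events = 25,
                             age_col = "age_imaging") {
  if (min_events < 1)
    abort_aac("min_events must be at least 1", "aac_validation_error")
  rows <- list()
  for (d in diseases) {
    ev <- paste0(d, "_event"); tm <- paste0(d, "_time")
    pr <- paste0(d, "_prior")
    if (!all(c(ev, tm, pr) %in% names(cohort)))
      abort_aac(sprintf("missing event/time/prior columns for '%s'", d),
                "aac_validation_error")
    sub <- cohort[cohort[[pr]] == 0, ]
    n_ev <- sum(sub[[ev]])
    if (n_ev <= min_events) next
    sub$.aac <- as.numeric(scale(sub$aac_score))
    fm <- as.formula(paste0("survival::Surv(", tm, ", ", ev, ") ~ .aac + ",
                            model_covariates(model, age_col)))
    fit <- survival::coxph(fm, data = sub, ties = "efron")
    sm <- summary(fit)
    co <- sm$coefficients[".aac", ]
    ci <- sm$conf.int[".aac", ]
    rows[[d]] <- data.frame(disease = d, hr = co[["exp(coef)"]],
                            ci_lo = ci[["lower .95"]],
                            ci_hi = ci[["upper .95"]],
                            p = co[["Pr(>|z|)"]],
                            n_events = n_ev, n = nrow(sub))
  }
  if (length(rows) == 0L) {
    warning("no disease passed the event filter")
    out <- data.frame(disease = character(), hr = numeric(),
                      ci_lo = numeric(), ci_hi = numeric(), p = numeric(),
                      p_bonferroni = numeric(), significant = logical(),
                      n_events = integer(), n = integer())
  } else {
    out <- do.call(rbind, rows)
    out$p_bonferroni <- pmin(1, out$p * nrow(out))
    out$significant <- out$p_bonferroni < 0.05
    out <- out[, c("disease", "hr", "ci_lo", "ci_hi", "p", "p_bonferroni",
                   "significant", "n_events", "n")]
    rownames(out) <- NULL
  }
  class(out) <- c("hazard_screen", "data.frame")
  out
}

#' Joint AAC / statin-adjusted-lipid hazard model for myocardial infarction
#'
#' Multivariate Cox model of the MI outcome on standardized AAC, statin-
#' adjusted LDL and triglycerides, age and sex, with an AAC x LDL
#' interaction test; runs on the whole cohort or on non-statin-users only.
#' Index date is the baseline visit (when lipids were measured), hence age
#' at baseline is the age covariate.
#'
#' @param cohort cohort `data.frame` with `mi_*` outcome columns (or the
#'   disease named by `disease`).
#' @param statin_model 0 (no adjustment: measured lipids), 1, 2 or 3
#'   (see [adjust_ldl_statin()]).
#' @param imputer `lipid_imputer` when `statin_model = 3`.
#' @param subset `"all"` or `"nonusers"`.
#' @param disease outcome name prefix (default `"mi"`).
#' @return List of class `joint_mi_fit`: `estimates` (HR per SD with CI and
#'   p for aac, ldl, triglycerides), `interaction_p` (AAC x LDL), `n`,
#'   `n_events`, `statin_model`, `subset`.
#' @export
joint_mi_model <- function(cohort, statin_model = 1, imputer = NULL,
                           subset = c("all", "nonusers"), disease = "mi") {
  subset <- match.arg(subset)
  dat <- cohort[cohort[[paste0(disease, "_prior")]] == 0, ]
  if (subset == "nonusers") dat <- dat[!dat$statin_user, ]
  adj <- if (statin_model == 0)
    data.frame(ldl_adjusted = dat$ldl, trig_adjusted = dat$triglycerides)
  else adjust_ldl_statin(dat$ldl, dat$triglycerides, dat$statin_user,
                         model = statin_model, imputer = imputer, data = dat)
  dat$.aac <- as.numeric(scale(dat$aac_score))
  dat$.ldl <- as.numeric(scale(adj$ldl_adjusted))
  dat$.trig <- as.numeric(scale(adj$trig_adjusted))
  base_fm <- paste0("survival::Surv(", disease, "_time, ", disease,
                    "_event) ~ .aac + .ldl + .trig + age_baseline + sex")
  fit <- survival::coxph(as.formula(base_fm), data = dat, ties = "efron")
  fit_int <- survival::coxph(as.formula(paste(base_fm, "+ .aac:.ldl")),
                             data = dat, ties = "efron")
  sm <- summary(fit)
  terms <- c(aac = ".aac", ldl = ".ldl", triglycerides = ".trig")
  est <- do.call(rbind, lapply(names(terms), function(nm) {
    co <- sm$coefficients[terms[[nm]], ]
    ci <- sm$conf.int[terms[[nm]], ]
    data.frame(term = nm, hr_per_sd = co[["exp(coef)"]],
               ci_lo = ci[["lower .95"]], ci_hi = ci[["upper .95"]],
               p = co[["Pr(>|z|)"]])
  }))
  rownames(est) <- NULL
  int_p <- summary(fit_int)$coefficients[".aac:.ldl", "Pr(>|z|)"]
  structure(list(estimates = est, interaction_p = int_p,
                 n = nrow(dat), n_events = sum(dat[[paste0(disease, "_event")]]),
                 statin_model = statin_model, subset = subset),
            class = "joint_mi_fit")
}

#' @export
print.joint_mi_fit <- function(x, ...) {
  cat(sprintf(
    "<joint_mi_fit> statin model %s, %s, n = %d (%d events)\n",
    x$statin_model, x$subset, x$n, x$n_events))
  print(transform(x$estimates, hr_per_sd = round(hr_per_sd, 3),
                  ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3),
                  p = signif(p, 3)))
  cat(sprintf("AAC x LDL interaction p = %.3g\n", x$interaction_p))
  invisible(x)
}
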