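## Marginal model of the AAC score in the population: a zero-inflated gamma
## whose frozen constants reproduce the observed regime of a mostly-healthy
## middle-aged cohort (mean total ~1.47 and ~11.6% of scores above 3).
aac_marginal_defaults <- function() {
  list(p_zero = 0.20, shape = 2.5846, scale = 0.71094)
}

## quantile function of the zero-inflated gamma marginal
qzig <- function(u, marg = aac_marginal_defaults()) {
  u <- pmin(u, 1 - 1e-12)
  out <- numeric(length(u))
  pos <- u > marg$p_zero
  out[pos] <- qgamma((u[pos] - marg$p_zero) / (1 - marg$p_zero),
                     shape = marg$shape, scale = marg$scale)
  pmin(out, 24)
}

## Covariate effects on AAC are specified on the score scale (score units
## per +1 SD, or per group for binaries) but applied on a latent Gaussian
## liability; this conversion factor is the local slope of the
## liability->score map, so small latent shifts produce the requested
## score-scale contrasts.
zig_liability_slope <- function(marg = aac_marginal_defaults(), delta = 0.1) {
  ev <- function(c) {
    integrate(function(z) qzig(pnorm(z + c), marg) * dnorm(z),
              -8, 8, rel.tol = 1e-9)$value
  }
  (ev(delta) - ev(-delta)) / (2 * delta)
}

#' Cohort simulation parameters
#'
#' Defaults encode the study conditions of a large middle-aged imaging
#' cohort: AAC marginal calibrated to mean ~1.47 with ~11.6% of scores
#' above 3; smoking and age as the strongest AAC predictors (score-scale
#' effect ~0.12 each); ~15% statin use assigned with confounding by
#' indication (probability increasing in untreated LDL and age); and a
#' myocardial-infarction outcome with true hazard ratio 1.4 per SD of AAC
#' and 1.4 per SD of untreated LDL, indexed at the baseline visit.
#'
#' @param aac_marginal list `p_zero`, `shape`, `scale` of the zero-inflated
#'   gamma score marginal.
#' @param aac_effects named score-scale effects on AAC (per SD for
#'   continuous covariates, per group for indicators).
#' @param biomarker_cor named correlations between each biomarker and the
#'   standardized AAC score (LDL deliberately 0).
#' @param statin_prevalence target marginal fraction of statin users.
#' @param statin_confounding logistic coefficients `c(ldl, age)` on the
#'   standardized untreated LDL and age driving statin assignment.
#' @param statin_effect treatment effect on measured lipids:
#'   `list(type = "proportional", reduction = 0.35)` or
#'   `list(type = "additive", ldl = 1.25, trig = 1.25)`.
#' @param diseases named list of disease configs, each with `hr_aac` (per SD
#'   of AAC), optional `hr_ldl`, `hr_trig` (per SD of untreated lipids),
#'   `hr_age`, `hr_sex`, `base_rate` (events per person-year at the
#'   baseline hazard), `horizon` (administrative censoring, years), `index`
#'   (`"imaging"` or `"baseline"`) and `prior_prob` (prior-history
#'   fraction, excluded from time-to-event analyses).
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(
    aac_marginal = aac_marginal_defaults(),
    aac_effects = c(age = 0.12, sex_male = 0.05, bmi = 0.05,
                    smoking_previous = 0.12, smoking_current = 0.12),
    biomarker_cor = c(ldl = 0, hdl = -0.08, triglycerides = 0.08,
                      glucose = 0.08, hba1c = 0.10, phosphate = 0.10,
                      calcium = 0.02, creatinine = -0.06, cystatin_c = 0.05),
    statin_prevalence = 0.15,
    statin_confounding = c(ldl = 0.9, age = 0.7),
    statin_effect = list(type = "proportional", reduction = 0.35),
    diseases = list(
      mi = list(hr_aac = 1.4, hr_ldl = 1.4, hr_trig = 1.1, hr_age = 1.5,
                hr_sex = 1.3, base_rate = 0.004, horizon = 12,
                index = "baseline", prior_prob = 0.02))) {
  for (d in diseases) {
    hrs <- unlist(d[grep("^hr_", names(d))])
    if (any(hrs <= 0))
      abort_aac("hazard ratios must be positive", "aac_validation_error")
  }
  structure(list(aac_marginal = aac_marginal, aac_effects = aac_effects,
                 biomarker_cor = biomarker_cor,
                 statin_prevalence = statin_prevalence,
                 statin_confounding = statin_confounding,
                 statin_effect = statin_effect, diseases = diseases),
            class = "cohort_params")
}

#' Generate a synthetic cohort
#'
#' Draws participant covariates, an AAC score with the configured marginal
#' and covariate effects, biomarkers with configured correlations to AAC,
#' statin use confounded by indication with lipid-lowering applied to the
#' *measured* lipids, and per-disease proportional-hazards event times with
#' administrative censoring. Ground-truth untreated lipid columns
#' (`ldl_untreated`, `triglycerides_untreated`) are retained for
#' recovery testing.
#'
#' @param n cohort size (>= 1).
#' @param params a [cohort_params()] list.
#' @param seed RNG seed.
#' @return A `data.frame` with one row per participant; per-disease columns
#'   `<name>_event`, `<name>_time` (years from the disease's index visit)
#'   and `<name>_prior`.
#' @export
generate_cohort <- function(n, params = cohort_params(), seed = 1L) {
  if (n < 1) abort_aac("n must be at least 1", "aac_validation_error")
  local_seed(seed, {
    age_baseline <- runif(n, 45, 70)
    age_imaging <- age_baseline + runif(n, 7, 10)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    bmi <- rnorm(n, 27, 4.2)
    smoking <- sample(c("never", "previous", "current"), n, replace = TRUE,
                      prob = c(0.56, 0.34, 0.10))
    ses <- rnorm(n)
    ethnicity <- sample(c("white", "asian", "black", "other"), n,
                        replace = TRUE, prob = c(0.94, 0.02, 0.02, 0.02))

    ## latent liability: score-scale effects translated to the latent scale
    s0 <- zig_liability_slope(params$aac_marginal)
    ef <- params$aac_effects / s0
    lp <- ef[["age"]] * scale(age_imaging)[, 1] +
      ef[["sex_male"]] * (sex == "male") +
      ef[["bmi"]] * scale(bmi)[, 1] +
      ef[["smoking_previous"]] * (smoking == "previous") +
      ef[["smoking_current"]] * (smoking == "current")
    lp <- lp - mean(lp)
    v <- var(lp)
    if (v >= 0.9) {
      warning("AAC covariate effects nearly exhaust the liability variance")
      lp <- lp * sqrt(0.9 / v); v <- 0.9
    }
    z <- lp + rnorm(n, 0, sqrt(1 - v))
    aac <- qzig(pnorm(z), params$aac_marginal)
    aac_std <- (aac - mean(aac)) / sd(aac)

    ## biomarkers: configured correlation with standardized AAC
    bm <- function(mu, sigma, rho, log_normal = FALSE) {
      zz <- rho * aac_std + sqrt(1 - rho^2) * rnorm(n)
      if (log_normal) exp(mu + sigma * zz) else mu + sigma * zz
    }
    rc <- params$biomarker_cor
    ## floor at a physiological minimum so additive statin masking cannot
    ## drive measured LDL negative
    ldl_u <- pmax(bm(3.6, 0.85, rc[["ldl"]]), 1.4)
    hdl <- pmax(bm(1.45, 0.37, rc[["hdl"]]), 0.3)
    trig_u <- bm(log(1.5), 0.45, rc[["triglycerides"]], log_normal = TRUE)
    glucose <- pmax(bm(5.0, 0.98, rc[["glucose"]]), 2.5)
    hba1c <- pmax(bm(35.9, 5.9, rc[["hba1c"]]), 20)
    phosphate <- pmax(bm(1.15, 0.16, rc[["phosphate"]]), 0.5)
    calcium <- bm(2.38, 0.09, rc[["calcium"]])
    creatinine <- pmax(bm(72, 14, rc[["creatinine"]]), 30)
    cystatin_c <- pmax(bm(0.90, 0.13, rc[["cystatin_c"]]), 0.4)
    sbp <- rnorm(n, 138, 18) + 4 * scale(age_baseline)[, 1]
    dbp <- rnorm(n, 82, 10)
    pulse <- rnorm(n, 69, 11)

    ## statin assignment: confounding by indication, marginal prevalence
    ## solved exactly for the drawn cohort
    w <- params$statin_confounding[["ldl"]] * scale(ldl_u)[, 1] +
      params$statin_confounding[["age"]] * scale(age_baseline)[, 1]
    a <- uniroot(function(a) mean(plogis(a + w)) - params$statin_prevalence,
                 c(-20, 20))$root
    statin_user <- runif(n) < plogis(a + w)

    se <- params$statin_effect
    if (se$type == "proportional") {
      ldl <- ifelse(statin_user, ldl_u * (1 - se$reduction), ldl_u)
      trig <- ifelse(statin_user, trig_u * (1 - se$reduction), trig_u)
    } else if (se$type == "additive") {
      ldl <- ifelse(statin_user, ldl_u - se$ldl, ldl_u)
      trig <- ifelse(statin_user, pmax(trig_u - se$trig, 0.05), trig_u)
    } else abort_aac("unknown statin_effect type", "aac_config_error")

    cohort <- data.frame(
      id = sprintf("P%06d", seq_len(n)),
      age_baseline = age_baseline, age_imaging = age_imaging, sex = sex,
      bmi = bmi, smoking = smoking, ses = ses, ethnicity = ethnicity,
      ldl = ldl, ldl_untreated = ldl_u, hdl = hdl,
      triglycerides = trig, triglycerides_untreated = trig_u,
      glucose = glucose, hba1c = hba1c, phosphate = phosphate,
      calcium = calcium, creatinine = creatinine, cystatin_c = cystatin_c,
      sbp = sbp, dbp = dbp, pulse = pulse,
      statin_user = statin_user, aac_score = aac,
      stringsAsFactors = FALSE)

    ## proportional-hazards event times per disease, exponential baseline
    ldl_u_std <- scale(ldl_u)[, 1]
    trig_u_std <- scale(log(trig_u))[, 1]
    age_std <- scale(age_baseline)[, 1]
    for (nm in names(params$diseases)) {
      d <- params$diseases[[nm]]
      g <- function(key, default = 1) if (is.null(d[[key]])) default else d[[key]]
      lph <- log(g("hr_aac")) * aac_std +
        log(g("hr_ldl")) * ldl_u_std +
        log(g("hr_trig")) * trig_u_std +
        log(g("hr_age", 1.5)) * age_std +
        log(g("hr_sex", 1.2)) * (sex == "male")
      horizon <- g("horizon", 3)
      t_raw <- rexp(n) / (g("base_rate", 0.01) * exp(lph))
      cohort[[paste0(nm, "_event")]] <- as.integer(t_raw <= horizon)
      cohort[[paste0(nm, "_time")]] <- pmin(t_raw, horizon)
      cohort[[paste0(nm, "_prior")]] <-
        as.integer(runif(n) < g("prior_prob", 0.03))
    }
    cohort
  })
}

#' Read and write cohort tables as CSV
#'
#' @param cohort cohort `data.frame`.
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
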