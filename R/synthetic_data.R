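# Synthetic cohort generator: a Gaussian-copula model of the six continuous
# cardiometabolic measures with age/sex-shifted marginals, plus conditional
# logistic models for treatment and history flags, calibrated so the default
# configuration reproduces the enrollment marginals of an urban Haitian adult
# cohort (criterion prevalences, metabolic-syndrome prevalence and its
# female-to-male gradient).

measure_names <- c("sbp", "dbp", "waist", "glucose", "hdl", "tg")

#' Configuration for the synthetic cohort generator
#'
#' Returns the default configuration, optionally overridden. Continuous
#' measures are drawn from a latent multivariate normal (the copula) and
#' mapped to age- and sex-shifted marginals; normal on the natural scale for
#' SBP, DBP, waist and HDL-C, lognormal for glucose and triglycerides.
#' Binary fields (treatment, history) come from logistic models on age and
#' the latent scores, so criterion co-occurrence emerges downstream rather
#' than being written directly.
#'
#' @param n Number of participants to generate.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param ... Named overrides of any default component (e.g. `female_fraction`,
#'   `measures`, `corr`, `missingness_rate`). Nested lists are merged.
#' @return A list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n = 2721, seed = 1, ...) {
  msr <- function(mean42_m, mean42_f, slope_m, slope_f, sd_m, sd_f, log = FALSE) {
    list(mean42 = c(male = mean42_m, female = mean42_f),
         slope = c(male = slope_m, female = slope_f),
         sd = c(male = sd_m, female = sd_f), log = log)
  }
  corr <- diag(6)
  dimnames(corr) <- list(measure_names, measure_names)
  set_r <- function(a, b, r) {
    corr[a, b] <<- r
    corr[b, a] <<- r
  }
  set_r("sbp", "dbp", 0.75)
  set_r("sbp", "waist", 0.35); set_r("dbp", "waist", 0.35)
  set_r("sbp", "glucose", 0.25); set_r("dbp", "glucose", 0.20)
  set_r("sbp", "hdl", -0.12); set_r("dbp", "hdl", -0.10)
  set_r("sbp", "tg", 0.22); set_r("dbp", "tg", 0.18)
  set_r("waist", "glucose", 0.30)
  set_r("waist", "hdl", -0.32)
  set_r("waist", "tg", 0.35)
  set_r("glucose", "hdl", -0.10)
  set_r("glucose", "tg", 0.30)
  set_r("hdl", "tg", -0.40)

  config <- list(
    n = n, seed = seed,
    female_fraction = 0.580,
    age_band_probs = c(0.287, 0.189, 0.175, 0.169, 0.179),
    age_band_edges = cbind(lower = c(18, 30, 40, 50, 60),
                           upper = c(29, 39, 49, 59, 72)),
    measures = list(
      sbp = msr(121.5, 121.5, 0.50, 0.50, 15, 15),
      dbp = msr(75.5, 75.5, 0.25, 0.25, 10, 10),
      waist = msr(82.5, 85.5, 0.12, 0.18, 10.5, 12),
      glucose = msr(4.466, 4.466, 0.003, 0.003, 0.120, 0.120, log = TRUE),
      hdl = msr(46.5, 50.2, 0, 0, 11.5, 11.5),
      tg = msr(4.443, 4.443, 0.004, 0.004, 0.49, 0.49, log = TRUE)
    ),
    corr = corr,
    reading_sd = 4,            # within-person noise per BP reading, mmHg
    first_reading_bias = 3,    # alerting effect on the discarded first reading
    treated_bp_effect = c(sbp = 8, dbp = 4),  # BP lowering among treated
    antihypertensive = list(intercept = -2.95, age = 0.90, z_bp = 1.10),
    glucose_treatment = list(intercept = -4.20, age = 0.80, z_glucose = 1.50),
    hdl_treatment_prob = 0.008,
    tg_treatment_prob = 0.008,
    pmh = list(intercept = -1.45, age = 0.50, z_bp = 0.85, z_glucose = 0.25,
               z_waist = 0.35),
    fh = list(intercept = -0.29, age = 0.10, z_bp = 0.25),
    smoking_prob = c(male = 0.121, female = 0.043),
    high_alcohol_prob = c(male = 0.068, female = 0.015),
    fruit_veg_lambda = 1.6,
    fruit_veg_ge5_prob = c(male = 0.001, female = 0.009),
    high_fat_prob = 0.868,
    inactive_prob = 0.494,
    education_secondary_prob = c(male = 0.268, female = 0.428),
    income_probs = c(le_1_usd_day = 0.124, usd_1_to_10_day = 0.701,
                     gt_10_usd_day = 0.175),
    fasting_fraction = 0.713,
    nonfasting_spike = list(intercept = -3.5, z_glucose = 0.8,
                            logmean = log(2.6), logsd = 0.25),
    pregnancy_rate = 0.06,     # among women aged under 45
    missingness_rate = 0.014   # per clinical field group
  )
  overrides <- list(...)
  config <- merge_config(config, overrides)
  validate_synthetic_config(config)
  class(config) <- "synthetic_cohort_config"
  config
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

validate_synthetic_config <- function(config) {
  probs <- c(config$female_fraction, config$age_band_probs,
             config$high_fat_prob, config$inactive_prob,
             config$fasting_fraction, config$pregnancy_rate,
             config$missingness_rate, config$smoking_prob,
             config$high_alcohol_prob, config$education_secondary_prob,
             config$income_probs, config$hdl_treatment_prob,
             config$tg_treatment_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(config$age_band_probs) - 1) > 0.01) {
    stop("age_band_probs must sum to 1")
  }
  R <- config$corr
  if (!isTRUE(all.equal(R, t(R)))) stop("correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("correlation matrix is not positive definite (eigenvalue %.4g)",
                 min(ev)))
  }
  invisible(config)
}

#' Generate a synthetic participant cohort
#'
#' Deterministic given the configured seed. Draws age band and sex, the
#' correlated latent scores, the continuous measures with their age/sex
#' shifts, three blood-pressure readings with within-person noise (and a
#' small alerting bias on the first, discarded, reading), then the treatment,
#' history and behavior fields from their conditional models. Pregnancy and
#' per-field missingness are injected last, at the configured rates, so the
#' generated table emulates raw enrollment data before exclusions.
#'
#' @param config A [synthetic_cohort_config()].
#' @return A cohort data frame in the dialect of [read_cohort_csv()].
#' @export
generate_cohort <- function(config = synthetic_cohort_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n

  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  band <- sample.int(5, n, replace = TRUE, prob = config$age_band_probs)
  lo <- config$age_band_edges[band, "lower"]
  hi <- config$age_band_edges[band, "upper"]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1))

  # latent scores: one correlated standard normal per measure
  z <- matrix(stats::rnorm(n * 6), nrow = n) %*% chol(config$corr)
  colnames(z) <- measure_names

  value <- matrix(NA_real_, n, 6, dimnames = list(NULL, measure_names))
  for (m in measure_names) {
    par <- config$measures[[m]]
    mu <- par$mean42[sex] + par$slope[sex] * (age - 42)
    value[, m] <- mu + par$sd[sex] * z[, m]
    if (par$log) value[, m] <- exp(value[, m])
  }

  age10 <- (age - 42) / 10
  on_antihypertensive <- stats::runif(n) < stats::plogis(
    config$antihypertensive$intercept + config$antihypertensive$age * age10 +
      config$antihypertensive$z_bp * z[, "sbp"])
  sbp_true <- pmax(60, value[, "sbp"] -
                     config$treated_bp_effect[["sbp"]] * on_antihypertensive)
  dbp_true <- pmax(40, value[, "dbp"] -
                     config$treated_bp_effect[["dbp"]] * on_antihypertensive)
  reading <- function(true, bias = 0) {
    round(pmin(pmax(true + bias + stats::rnorm(n, 0, config$reading_sd), 40), 290))
  }
  sbp1 <- reading(sbp_true, config$first_reading_bias)
  sbp2 <- reading(sbp_true)
  sbp3 <- reading(sbp_true)
  dbp1 <- reading(dbp_true, config$first_reading_bias / 2)
  dbp2 <- reading(dbp_true)
  dbp3 <- reading(dbp_true)

  fasting <- stats::runif(n) < config$fasting_fraction
  glucose <- value[, "glucose"]
  spike <- !fasting & (stats::runif(n) < stats::plogis(
    config$nonfasting_spike$intercept +
      config$nonfasting_spike$z_glucose * z[, "glucose"]))
  glucose[spike] <- glucose[spike] *
    stats::rlnorm(sum(spike), config$nonfasting_spike$logmean,
                  config$nonfasting_spike$logsd)

  on_glucose_treatment <- stats::runif(n) < stats::plogis(
    config$glucose_treatment$intercept + config$glucose_treatment$age * age10 +
      config$glucose_treatment$z_glucose * z[, "glucose"])
  on_hdl_treatment <- stats::runif(n) < config$hdl_treatment_prob
  on_tg_treatment <- stats::runif(n) < config$tg_treatment_prob

  pmh_cvd <- stats::runif(n) < stats::plogis(
    config$pmh$intercept + config$pmh$age * age10 +
      config$pmh$z_bp * z[, "sbp"] + config$pmh$z_glucose * z[, "glucose"] +
      config$pmh$z_waist * z[, "waist"])
  fh_cvd <- stats::runif(n) < stats::plogis(
    config$fh$intercept + config$fh$age * age10 + config$fh$z_bp * z[, "sbp"])

  smoking <- ifelse(stats::runif(n) < config$smoking_prob[sex],
                    "current_former", "never")
  high_alcohol <- stats::runif(n) < config$high_alcohol_prob[sex]
  alcohol_per_week <- ifelse(high_alcohol, 5 + stats::rpois(n, 2),
                             pmin(stats::rpois(n, 0.8), 4))
  fruit_veg <- pmin(stats::rpois(n, config$fruit_veg_lambda), 4)
  ge5 <- stats::runif(n) < config$fruit_veg_ge5_prob[sex]
  fruit_veg[ge5] <- 5 + stats::rpois(sum(ge5), 1)
  fat_intake <- ifelse(stats::runif(n) < config$high_fat_prob, "high", "low")
  physically_inactive <- stats::runif(n) < config$inactive_prob
  education <- ifelse(stats::runif(n) < config$education_secondary_prob[sex],
                      "secondary_or_higher", "less_than_secondary")
  income_band <- sample(names(config$income_probs), n, replace = TRUE,
                        prob = config$income_probs)
  pregnant <- sex == "female" & age < 45 &
    stats::runif(n) < config$pregnancy_rate

  cohort <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = as.integer(age), sex = sex, education = education,
    income_band = income_band,
    sbp1 = sbp1, sbp2 = sbp2, sbp3 = sbp3,
    dbp1 = dbp1, dbp2 = dbp2, dbp3 = dbp3,
    on_antihypertensive = on_antihypertensive,
    waist_cm = round(pmin(pmax(value[, "waist"], 45), 250), 1),
    glucose_mgdl = round(pmin(glucose, 900)),
    fasting = fasting,
    on_glucose_treatment = on_glucose_treatment,
    hdl_mgdl = round(pmin(pmax(value[, "hdl"], 10), 150)),
    on_hdl_treatment = on_hdl_treatment,
    tg_mgdl = round(pmin(pmax(value[, "tg"], 20), 950)),
    on_tg_treatment = on_tg_treatment,
    pmh_cvd = pmh_cvd, fh_cvd = fh_cvd,
    smoking = smoking, alcohol_per_week = alcohol_per_week,
    fruit_veg_servings_day = fruit_veg, fat_intake = fat_intake,
    physically_inactive = physically_inactive, pregnant = pregnant,
    stringsAsFactors = FALSE
  )

  # per-field-group missingness, emulating incomplete enrollment records
  if (config$missingness_rate > 0) {
    groups <- list(c("sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3"),
                   "waist_cm", c("glucose_mgdl", "fasting"), "hdl_mgdl",
                   "tg_mgdl")
    for (g in groups) {
      hit <- stats::runif(n) < config$missingness_rate
      for (col in g) cohort[[col]][hit] <- NA
    }
  }
  cohort
}

#' Published marginal targets for generator calibration
#'
#' Criterion and syndrome prevalences of the analyzed urban Haitian adult
#' cohort (n = 2,721) used as calibration targets: fractions of the analysis
#' set unless noted.
#'
#' @return A named numeric vector of target proportions.
#' @export
default_calibration_targets <- function() {
  c(
    female = 0.580,
    e_bp = 0.390,
    e_wc = 0.449,
    low_hdl = 0.406,
    e_tg = 0.135,
    e_glu_fasting = 0.151,          # measured >= 100 among fasting
    on_antihypertensive = 0.124,
    pmh = 0.259,
    fh = 0.436,
    smoke_or_alcohol = 0.101,
    high_fat = 0.868,
    mets_h = 578 / 2721,
    mets_1 = 611 / 2721,
    mets_2 = 616 / 2721,
    mets_3 = 603 / 2721,
    mets_h_female = 0.291,
    mets_h_male = 0.104,
    e_bp_given_mets_h = 0.829,
    e_wc_given_mets_h = 0.907,
    low_hdl_given_mets_h = 0.817
  )
}

#' Compare simulated cohort marginals with calibration targets
#'
#' Applies the standard exclusions and classification to a generated cohort,
#' computes the observed analogue of every target and flags gaps beyond the
#' tolerance.
#'
#' @param cohort A generated cohort data frame.
#' @param targets Named target proportions, see
#'   [default_calibration_targets()].
#' @param thresholds Criterion thresholds.
#' @param tolerance Absolute gap (proportion scale) above which a quantity is
#'   flagged.
#' @return A data frame `quantity`, `simulated`, `target`, `gap`, `flagged`.
#' @export
calibration_report <- function(cohort, targets = default_calibration_targets(),
                               thresholds = default_thresholds(),
                               tolerance = 0.02) {
  cohort <- derive_measures(cohort)
  analysis <- apply_exclusions(cohort)$analysis
  calls <- classify_cohort(analysis, thresholds)
  pos <- function(col) calls[[col]] == "positive"
  mh <- pos("mets_h")
  fasting <- !is.na(analysis$fasting) & analysis$fasting

  sim <- c(
    female = mean(analysis$sex == "female"),
    e_bp = mean(calls$e_bp, na.rm = TRUE),
    e_wc = mean(calls$e_wc, na.rm = TRUE),
    low_hdl = mean(calls$low_hdl, na.rm = TRUE),
    e_tg = mean(calls$e_tg, na.rm = TRUE),
    e_glu_fasting = mean(analysis$glucose_mgdl[fasting] >= 100, na.rm = TRUE),
    on_antihypertensive = mean(analysis$on_antihypertensive, na.rm = TRUE),
    pmh = mean(calls$pmh, na.rm = TRUE),
    fh = mean(calls$fh, na.rm = TRUE),
    smoke_or_alcohol = mean(calls$smoke_or_alcohol, na.rm = TRUE),
    high_fat = mean(calls$high_fat, na.rm = TRUE),
    mets_h = mean(mh),
    mets_1 = mean(pos("mets_1")),
    mets_2 = mean(pos("mets_2")),
    mets_3 = mean(pos("mets_3")),
    mets_h_female = mean(mh[analysis$sex == "female"]),
    mets_h_male = mean(mh[analysis$sex == "male"]),
    e_bp_given_mets_h = mean(calls$e_bp[mh], na.rm = TRUE),
    e_wc_given_mets_h = mean(calls$e_wc[mh], na.rm = TRUE),
    low_hdl_given_mets_h = mean(calls$low_hdl[mh], na.rm = TRUE)
  )

  common <- intersect(names(targets), names(sim))
  out <- data.frame(
    quantity = common,
    simulated = unname(sim[common]),
    target = unname(targets[common]),
    stringsAsFactors = FALSE
  )
  out$gap <- abs(out$simulated - out$target)
  out$flagged <- out$gap > tolerance
  out
}

#' Simulate a binary outcome with known prevalence ratios
#'
#' Draws the age-band and sex structure of the cohort design and a Bernoulli
#' outcome whose prevalence follows a log-linear model with the supplied true
#' ratios — the known-truth generator used in parameter-recovery studies of
#' the regression module.
#'
#' @param n Sample size.
#' @param baseline Outcome prevalence in the joint reference cell (men under
#'   30).
#' @param sex_pr True female-vs-male prevalence ratio.
#' @param age_band_pr True prevalence ratios for the five age bands
#'   (reference first, so the first entry is 1).
#' @param female_fraction,age_band_probs Population structure.
#' @param seed Optional seed.
#' @return A data frame with `sex`, `age_band` and logical `y`.
#' @export
simulate_prevalence_outcome <- function(n, baseline = 0.0225, sex_pr = 2.47,
                                        age_band_pr = c(1, 2.57, 6.79, 9.41, 8.59),
                                        female_fraction = 0.58,
                                        age_band_probs = c(0.287, 0.189, 0.175,
                                                           0.169, 0.179),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(age_band_pr) == 5, age_band_pr[1] == 1)
  bands <- default_age_bands()$label
  sex <- ifelse(stats::runif(n) < female_fraction, "female", "male")
  band <- sample.int(5, n, replace = TRUE, prob = age_band_probs)
  p <- baseline * age_band_pr[band] * ifelse(sex == "female", sex_pr, 1)
  if (any(p > 1)) stop("true prevalences exceed 1; lower the baseline")
  data.frame(
    sex = sex,
    age_band = factor(bands[band], levels = bands),
    y = stats::runif(n) < p,
    stringsAsFactors = FALSE
  )
}
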