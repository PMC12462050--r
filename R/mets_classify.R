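# Criteria engine: the nine screening criteria and the four metabolic-syndrome
# definitions (laboratory-based harmonized reference plus three nonlaboratory
# screening rules).

criterion_names <- c("e_bp", "e_wc", "e_glu", "low_hdl", "e_tg",
                     "pmh", "fh", "high_fat", "smoke_or_alcohol")

#' Default criterion thresholds
#'
#' The harmonized-definition cutoffs with the IDF sub-Saharan Africa waist
#' values: SBP 130 / DBP 85 mmHg, waist 94 cm (men) / 80 cm (women), glucose
#' 100 mg/dL fasting / 200 mg/dL nonfasting, HDL-C 40 (men) / 50 (women)
#' mg/dL, triglycerides 150 mg/dL. Each elevated-type threshold carries an
#' `inclusive` flag: `TRUE` compares with `>=` (the default), `FALSE` with
#' `>`. For the reduced-HDL criterion `inclusive = TRUE` means strict `<`,
#' the harmonized wording.
#'
#' @return A named list of `list(value, inclusive)` entries.
#' @export
default_thresholds <- function() {
  thr <- function(value, inclusive = TRUE) list(value = value, inclusive = inclusive)
  list(
    sbp = thr(130), dbp = thr(85),
    waist_male = thr(94), waist_female = thr(80),
    glucose_fasting = thr(100), glucose_nonfasting = thr(200),
    hdl_male = thr(40), hdl_female = thr(50),
    tg = thr(150)
  )
}

#' Read or write a threshold configuration as JSON
#'
#' @param path File path.
#' @param thresholds A threshold list as from [default_thresholds()].
#' @return `read_thresholds` returns the threshold list; `write_thresholds`
#'   returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  thr <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- default_thresholds()
  missing <- setdiff(names(defaults), names(thr))
  if (length(missing) > 0) {
    stop("threshold config missing entries: ", paste(missing, collapse = ", "))
  }
  lapply(thr[names(defaults)], function(x) {
    list(value = as.numeric(x$value), inclusive = isTRUE(x$inclusive))
  })
}

#' @rdname read_thresholds
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(thresholds, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# x at or above an elevated-type threshold (>= when inclusive, > otherwise);
# propagates NA.
at_least <- function(x, thr) {
  if (thr$inclusive) x >= thr$value else x > thr$value
}
# x below a reduced-type threshold (< when inclusive, <= otherwise).
below <- function(x, thr) {
  if (thr$inclusive) x < thr$value else x <= thr$value
}

#' Evaluate the nine screening criteria for each participant
#'
#' Missingness follows three-valued logic: a criterion is `NA` only when the
#' available inputs cannot decide it (for example, normal measured values but
#' a missing treatment flag leave an OR-criterion undecided, while a single
#' elevated reading decides it regardless of the other inputs). A treatment
#' flag alone suffices to set its criterion.
#'
#' @param cohort A cohort data frame after [derive_measures()].
#' @param thresholds Threshold configuration, see [default_thresholds()].
#' @return A data frame with `id` and one logical column per criterion.
#' @export
derive_criteria <- function(cohort, thresholds = default_thresholds()) {
  if (!"mean_sbp" %in% names(cohort)) cohort <- derive_measures(cohort)
  sex <- cohort$sex
  bad_sex <- !is.na(sex) & !(sex %in% c("male", "female"))
  if (any(bad_sex)) {
    stop("unknown sex code: ", paste(unique(sex[bad_sex]), collapse = ", "))
  }

  col <- function(name) if (name %in% names(cohort)) cohort[[name]] else NA

  e_bp <- at_least(cohort$mean_sbp, thresholds$sbp) |
    at_least(cohort$mean_dbp, thresholds$dbp) |
    col("on_antihypertensive")

  wc_thr_val <- ifelse(sex == "male", thresholds$waist_male$value,
                       thresholds$waist_female$value)
  stopifnot(thresholds$waist_male$inclusive == thresholds$waist_female$inclusive)
  e_wc <- if (thresholds$waist_male$inclusive) {
    cohort$waist_cm >= wc_thr_val
  } else {
    cohort$waist_cm > wc_thr_val
  }

  glu_thr_val <- ifelse(col("fasting"), thresholds$glucose_fasting$value,
                        thresholds$glucose_nonfasting$value)
  stopifnot(thresholds$glucose_fasting$inclusive ==
              thresholds$glucose_nonfasting$inclusive)
  glu_high <- if (thresholds$glucose_fasting$inclusive) {
    cohort$glucose_mgdl >= glu_thr_val
  } else {
    cohort$glucose_mgdl > glu_thr_val
  }
  # with an unknown fasting state, only values elevated under both thresholds
  # (or normal under both) are decidable
  unknown_fast <- is.na(col("fasting")) & !is.na(cohort$glucose_mgdl)
  both_high <- at_least(cohort$glucose_mgdl,
                        list(value = max(thresholds$glucose_fasting$value,
                                         thresholds$glucose_nonfasting$value),
                             inclusive = thresholds$glucose_fasting$inclusive))
  both_low <- !at_least(cohort$glucose_mgdl,
                        list(value = min(thresholds$glucose_fasting$value,
                                         thresholds$glucose_nonfasting$value),
                             inclusive = thresholds$glucose_fasting$inclusive))
  glu_high[unknown_fast] <- ifelse(both_high[unknown_fast], TRUE,
                                   ifelse(both_low[unknown_fast], FALSE, NA))
  e_glu <- glu_high | col("on_glucose_treatment")

  hdl_thr_val <- ifelse(sex == "male", thresholds$hdl_male$value,
                        thresholds$hdl_female$value)
  stopifnot(thresholds$hdl_male$inclusive == thresholds$hdl_female$inclusive)
  hdl_low <- if (thresholds$hdl_male$inclusive) {
    cohort$hdl_mgdl < hdl_thr_val
  } else {
    cohort$hdl_mgdl <= hdl_thr_val
  }
  low_hdl <- hdl_low | col("on_hdl_treatment")

  e_tg <- at_least(cohort$tg_mgdl, thresholds$tg) | col("on_tg_treatment")

  smoke_or_alcohol <- (col("smoking") == "current_former") | col("high_alcohol")

  data.frame(
    id = cohort$id,
    e_bp = e_bp, e_wc = e_wc, e_glu = e_glu, low_hdl = low_hdl, e_tg = e_tg,
    pmh = as.logical(col("pmh_cvd")), fh = as.logical(col("fh_cvd")),
    high_fat = col("fat_intake") == "high",
    smoke_or_alcohol = smoke_or_alcohol,
    stringsAsFactors = FALSE
  )
}

#' The four metabolic-syndrome definitions
#'
#' `MetS-H` is the laboratory-based harmonized reference (any 3 of elevated
#' BP, elevated waist, elevated glucose, reduced HDL-C, elevated
#' triglycerides). The nonlaboratory screening rules are `MetS-1` (elevated
#' BP and elevated waist, both required), `MetS-2` (3 of: elevated BP,
#' elevated waist, personal history, family history) and `MetS-3` (4 of:
#' the MetS-2 criteria plus high fat intake and smoking-or-high-alcohol).
#'
#' @return A named list of definitions, each `list(name, criteria, min_count)`.
#' @export
mets_definitions <- function() {
  def <- function(name, criteria, min_count) {
    list(name = name, criteria = criteria, min_count = min_count)
  }
  list(
    `MetS-H` = def("MetS-H", c("e_bp", "e_wc", "e_glu", "low_hdl", "e_tg"), 3),
    `MetS-1` = def("MetS-1", c("e_bp", "e_wc"), 2),
    `MetS-2` = def("MetS-2", c("e_bp", "e_wc", "pmh", "fh"), 3),
    `MetS-3` = def("MetS-3", c("e_bp", "e_wc", "pmh", "fh", "high_fat",
                               "smoke_or_alcohol"), 4)
  )
}

#' Apply a definition to a criterion profile
#'
#' A profile is positive when at least `min_count` of the definition's
#' criteria are true; indeterminate when the criteria known to be true fall
#' short but the missing ones could still reach the count; negative
#' otherwise.
#'
#' @param profile Named logical vector (or one-row data frame) of criteria;
#'   `NA` marks a criterion undecidable from the available data.
#' @param definition One entry of [mets_definitions()].
#' @return `"positive"`, `"negative"` or `"indeterminate"`.
#' @export
classify <- function(profile, definition) {
  if (is.data.frame(profile)) profile <- unlist(profile[1, , drop = TRUE])
  missing_crit <- setdiff(definition$criteria, names(profile))
  if (length(missing_crit) > 0) {
    stop("profile lacks criteria: ", paste(missing_crit, collapse = ", "))
  }
  vals <- as.logical(profile[definition$criteria])
  n_true <- sum(vals, na.rm = TRUE)
  n_na <- sum(is.na(vals))
  if (n_true >= definition$min_count) "positive"
  else if (n_true + n_na >= definition$min_count) "indeterminate"
  else "negative"
}

#' Classify a whole analysis set under all four definitions
#'
#' @param cohort A cohort data frame (exclusions already applied).
#' @param thresholds Threshold configuration.
#' @param definitions Definitions to apply; defaults to all four.
#' @return A data frame with `id`, the nine criterion columns and one call
#'   column per definition (`mets_h`, `mets_1`, ...), values in
#'   positive/negative/indeterminate.
#' @export
classify_cohort <- function(cohort, thresholds = default_thresholds(),
                            definitions = mets_definitions()) {
  crit <- derive_criteria(cohort, thresholds)
  out <- crit
  for (def in definitions) {
    vals <- as.matrix(crit[, def$criteria, drop = FALSE])
    n_true <- rowSums(vals, na.rm = TRUE)
    n_na <- rowSums(is.na(vals))
    call <- ifelse(n_true >= def$min_count, "positive",
                   ifelse(n_true + n_na >= def$min_count, "indeterminate",
                          "negative"))
    out[[call_column(def$name)]] <- call
  }
  out
}

# "MetS-H" -> "mets_h"
call_column <- function(name) {
  gsub("-", "_", tolower(name), fixed = TRUE)
}
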