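# Domain model for participant-level cohort tables: plausibility validation,
# derived measures (mean BP, behavior categories) and analysis-set exclusions.

#' Plausibility windows for clinical measurements
#'
#' Closed intervals of biologically plausible values used when validating a
#' cohort table. Blood-pressure windows apply to every repeated reading.
#' Glucose has no finite upper window but must be strictly positive.
#'
#' @return A data frame with columns `field`, `lower`, `upper` and
#'   `lower_strict` (`TRUE` when the lower bound is exclusive).
#' @export
plausibility_windows <- function() {
  data.frame(
    field = c("sbp", "dbp", "waist_cm", "glucose_mgdl", "hdl_mgdl", "tg_mgdl"),
    lower = c(40, 30, 30, 0, 0, 0),
    upper = c(300, 200, 300, Inf, 200, 1000),
    lower_strict = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Column dictionary for the cohort CSV dialect.
cohort_numeric_cols <- c(
  "age", "sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3", "waist_cm",
  "glucose_mgdl", "hdl_mgdl", "tg_mgdl", "alcohol_per_week",
  "fruit_veg_servings_day"
)
cohort_logical_cols <- c(
  "on_antihypertensive", "fasting", "on_glucose_treatment", "on_hdl_treatment",
  "on_tg_treatment", "pmh_cvd", "fh_cvd", "physically_inactive", "pregnant"
)
cohort_factor_cols <- list(
  sex = c("male", "female"),
  education = c("less_than_secondary", "secondary_or_higher"),
  income_band = c("le_1_usd_day", "usd_1_to_10_day", "gt_10_usd_day"),
  smoking = c("current_former", "never"),
  fat_intake = c("high", "low")
)

# Condition columns that may replace a pre-aggregated composite flag; the
# reader ORs them together.
pmh_condition_cols <- paste0("pmh_", c(
  "hypertension", "high_cholesterol", "diabetes", "mi_angina", "arrhythmia",
  "heart_failure", "cvd_hospitalization"
))
fh_condition_cols <- paste0("fh_", c(
  "stroke", "hypertension", "mi_angina", "heart_failure", "cardiac_death"
))

#' Read a participant cohort table from CSV
#'
#' One row per participant; empty strings are read as missing values and
#' 0/1 columns become logicals. Repeated blood-pressure readings live in wide
#' columns `sbp1..sbp3` / `dbp1..dbp3`. Composite history flags may arrive
#' either pre-aggregated (`pmh_cvd`, `fh_cvd`) or as per-condition columns
#' (`pmh_*`, `fh_*`) that are ORed together; a single `on_lipid_treatment`
#' column is mapped to both the HDL and triglyceride treatment flags.
#'
#' @param path Path to a cohort CSV file.
#' @return A data frame in the package's cohort dialect.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  if (!"id" %in% names(raw)) stop("cohort CSV must have an 'id' column")
  raw$id <- as.character(raw$id)

  for (col in intersect(cohort_numeric_cols, names(raw))) {
    v <- raw[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(conv)
      if (any(bad)) {
        stop(sprintf("non-numeric value in numeric field '%s': %s",
                     col, paste(unique(v[bad]), collapse = ", ")))
      }
      raw[[col]] <- conv
    } else {
      raw[[col]] <- as.numeric(v)
    }
  }

  if (!"pmh_cvd" %in% names(raw) && any(pmh_condition_cols %in% names(raw))) {
    raw$pmh_cvd <- or_across(raw, intersect(pmh_condition_cols, names(raw)))
  }
  if (!"fh_cvd" %in% names(raw) && any(fh_condition_cols %in% names(raw))) {
    raw$fh_cvd <- or_across(raw, intersect(fh_condition_cols, names(raw)))
  }
  if ("on_lipid_treatment" %in% names(raw)) {
    if (!"on_hdl_treatment" %in% names(raw)) {
      raw$on_hdl_treatment <- raw$on_lipid_treatment
    }
    if (!"on_tg_treatment" %in% names(raw)) {
      raw$on_tg_treatment <- raw$on_lipid_treatment
    }
  }

  for (col in intersect(cohort_logical_cols, names(raw))) {
    raw[[col]] <- as_cohort_logical(raw[[col]], col)
  }
  for (col in intersect(names(cohort_factor_cols), names(raw))) {
    bad <- !is.na(raw[[col]]) & !(raw[[col]] %in% cohort_factor_cols[[col]])
    if (any(bad)) {
      stop(sprintf("unknown code in '%s': %s", col,
                   paste(unique(raw[[col]][bad]), collapse = ", ")))
    }
  }
  raw
}

or_across <- function(df, cols) {
  out <- rep(FALSE, nrow(df))
  for (col in cols) out <- out | as_cohort_logical(df[[col]], col)
  out
}

as_cohort_logical <- function(v, col) {
  if (is.logical(v)) return(v)
  if (is.numeric(v)) {
    if (any(!is.na(v) & !(v %in% c(0, 1)))) {
      stop(sprintf("boolean column '%s' must be 0/1", col))
    }
    return(v == 1)
  }
  out <- rep(NA, length(v))
  out[v %in% c("1", "TRUE", "true")] <- TRUE
  out[v %in% c("0", "FALSE", "false")] <- FALSE
  if (any(is.na(out) & !is.na(v))) {
    stop(sprintf("boolean column '%s' must be 0/1", col))
  }
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort_csv()]: logicals are serialized as 0/1 and missing
#' values as empty strings, so a seed-fixed synthetic cohort round-trips
#' byte-for-byte.
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  for (col in intersect(cohort_logical_cols, names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort against the plausibility windows
#'
#' Checks every present numeric measurement against [plausibility_windows()]
#' and the record-level invariants (age at least 18, known sex codes). The
#' report is empty iff every present value lies inside its window; each
#' violation names the offending column, the value and the window.
#'
#' @param cohort A cohort data frame (see [read_cohort_csv()]).
#' @return A data frame with columns `id`, `field`, `value`, `lower`, `upper`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(all(c("id", "age", "sex") %in% names(cohort)))
  win <- plausibility_windows()
  viol <- list()
  add <- function(id, field, value, lower, upper) {
    data.frame(id = id, field = field, value = value, lower = lower,
               upper = upper, stringsAsFactors = FALSE)
  }

  check_window <- function(col, window_field) {
    if (!col %in% names(cohort)) return(NULL)
    w <- win[win$field == window_field, ]
    v <- cohort[[col]]
    if (!is.numeric(v)) stop(sprintf("field '%s' is not numeric", col))
    low_bad <- if (w$lower_strict) v <= w$lower else v < w$lower
    bad <- !is.na(v) & (low_bad | v > w$upper)
    if (!any(bad)) return(NULL)
    add(cohort$id[bad], col, v[bad], w$lower, w$upper)
  }

  for (col in c("sbp1", "sbp2", "sbp3")) viol <- c(viol, list(check_window(col, "sbp")))
  for (col in c("dbp1", "dbp2", "dbp3")) viol <- c(viol, list(check_window(col, "dbp")))
  for (col in c("waist_cm", "glucose_mgdl", "hdl_mgdl", "tg_mgdl")) {
    viol <- c(viol, list(check_window(col, col)))
  }

  bad_age <- !is.na(cohort$age) & cohort$age < 18
  if (any(bad_age)) {
    viol <- c(viol, list(add(cohort$id[bad_age], "age", cohort$age[bad_age], 18, Inf)))
  }

  out <- do.call(rbind, viol)
  if (is.null(out)) {
    out <- data.frame(id = character(), field = character(), value = numeric(),
                      lower = numeric(), upper = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Derive analysis measures from raw readings
#'
#' Adds to the cohort: `mean_sbp` / `mean_dbp` (the average of the second and
#' third blood-pressure readings when three are present; with fewer readings
#' the mean of whatever is available, flagged in `bp_fallback`), `high_alcohol`
#' (5 or more drinking occasions per week) and `low_fruit_veg` (fewer than 5
#' servings per day). A participant with no readings at all gets a missing
#' mean, not an error.
#'
#' @param cohort A validated cohort data frame.
#' @return The cohort with derived columns appended.
#' @export
derive_measures <- function(cohort) {
  mean_23 <- function(prefix) {
    m <- as.matrix(cohort[, paste0(prefix, 1:3)[paste0(prefix, 1:3) %in% names(cohort)],
                          drop = FALSE])
    apply(m, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) >= 3) mean(r[2:3]) else if (length(r) >= 1) mean(r) else NA_real_
    })
  }
  n_readings <- function(prefix) {
    m <- as.matrix(cohort[, paste0(prefix, 1:3)[paste0(prefix, 1:3) %in% names(cohort)],
                          drop = FALSE])
    rowSums(!is.na(m))
  }
  cohort$mean_sbp <- mean_23("sbp")
  cohort$mean_dbp <- mean_23("dbp")
  cohort$bp_fallback <- pmin(n_readings("sbp"), n_readings("dbp")) < 3 &
    pmax(n_readings("sbp"), n_readings("dbp")) > 0
  cohort$high_alcohol <- if ("alcohol_per_week" %in% names(cohort)) {
    cohort$alcohol_per_week >= 5
  } else NA
  cohort$low_fruit_veg <- if ("fruit_veg_servings_day" %in% names(cohort)) {
    cohort$fruit_veg_servings_day < 5
  } else NA
  cohort
}

#' Split a cohort into the analysis set and an exclusion log
#'
#' Excludes participants who were pregnant at enrollment and participants
#' missing any field required to evaluate the screening criteria. A missing
#' pregnancy flag is treated as not pregnant: exclusion requires an
#' affirmative flag. Every input row lands in exactly one of the two outputs.
#'
#' @param cohort A cohort data frame, normally after [derive_measures()].
#' @param required_fields Character vector of column names that must be
#'   non-missing for a participant to enter the analysis set. The default
#'   covers the inputs of the laboratory-based definition.
#' @return A list with `analysis` (data frame) and `exclusions` (data frame
#'   with `id` and semicolon-separated `reason`).
#' @export
apply_exclusions <- function(cohort,
                             required_fields = c("mean_sbp", "mean_dbp",
                                                 "waist_cm", "glucose_mgdl",
                                                 "fasting", "hdl_mgdl",
                                                 "tg_mgdl")) {
  required_fields <- intersect(required_fields, names(cohort))
  pregnant <- if ("pregnant" %in% names(cohort)) {
    !is.na(cohort$pregnant) & cohort$pregnant
  } else rep(FALSE, nrow(cohort))

  miss_mat <- vapply(required_fields, function(f) is.na(cohort[[f]]),
                     logical(nrow(cohort)))
  miss_mat <- matrix(miss_mat, nrow = nrow(cohort),
                     dimnames = list(NULL, required_fields))
  reasons <- lapply(seq_len(nrow(cohort)), function(i) {
    c(if (pregnant[i]) "pregnant",
      paste0("missing:", required_fields[miss_mat[i, ]], recycle0 = TRUE))
  })
  excluded <- lengths(reasons) > 0

  exclusions <- data.frame(
    id = cohort$id[excluded],
    reason = vapply(reasons[excluded], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  list(analysis = cohort[!excluded, , drop = FALSE], exclusions = exclusions)
}

#' Tabulate exclusion reasons
#'
#' @param exclusions The exclusion log from [apply_exclusions()].
#' @return A data frame of reason counts (a participant excluded for several
#'   reasons contributes to each).
#' @export
exclusion_counts <- function(exclusions) {
  reasons <- unlist(strsplit(exclusions$reason, ";", fixed = TRUE))
  if (length(reasons) == 0) {
    return(data.frame(reason = character(), n = integer()))
  }
  tab <- table(reasons)
  data.frame(reason = names(tab), n = as.integer(tab), row.names = NULL,
             stringsAsFactors = FALSE)
}
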