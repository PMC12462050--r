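# Pipeline orchestration: run the whole analysis on a cohort CSV or a
# generated cohort and write the report bundle; or replay pre-tabulated 2x2
# cells (tables mode) so printed comparison tables can be re-analyzed
# without participant-level data.

#' Half-up rounding for presentation tables
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values; ties go away from zero (so 0.25 to one decimal
#'   is 0.3), matching how the report tables print percentages. A small fuzz
#'   keeps decimal ties that have no exact binary representation (91.55)
#'   rounding up.
#' @export
round_half_up <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of `input` (cohort CSV path or cohort data frame) and
#' `generator` (a [synthetic_cohort_config()]) must be supplied.
#'
#' @param input Cohort CSV path or data frame, or `NULL`.
#' @param generator Generator configuration, or `NULL`.
#' @param thresholds Criterion thresholds.
#' @param standard Standard population data frame (5-year bands); default the
#'   embedded WHO 2000-2025 World Standard.
#' @param out_dir Output directory for the report bundle.
#' @param definitions Names of the definitions to analyze (the reference
#'   `MetS-H` is always included).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL,
                       thresholds = default_thresholds(),
                       standard = NULL, out_dir = NULL,
                       definitions = c("MetS-1", "MetS-2", "MetS-3")) {
  if (is.null(input) == is.null(generator)) {
    stop("supply exactly one of 'input' and 'generator'")
  }
  structure(list(input = input, generator = generator,
                 thresholds = thresholds, standard = standard,
                 out_dir = out_dir, definitions = definitions),
            class = "run_config")
}

write_table <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
}

#' Run the full analysis pipeline
#'
#' Reads (or generates) a cohort, validates it, applies exclusions,
#' classifies under the configured definitions and produces: the exclusion
#' log, a descriptive characteristics table, a criterion-by-definition
#' table, the 2x2 comparison of each screening definition against the
#' laboratory-based reference with kappa, diagnostic accuracy overall and by
#' sex, crude/stratified/age-standardized prevalence, prevalence-ratio
#' regressions (log-binomial with robust-Poisson and logistic sensitivity
#' columns), and a provenance block echoing thresholds and seed. All tables
#' are returned and, when `out_dir` is set, written as full-precision CSVs
#' (provenance as JSON). Runs on the same seed are byte-identical.
#'
#' @param config A [run_config()].
#' @return A list of class `report_bundle` with the tables above.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  cohort <- if (!is.null(config$generator)) {
    generate_cohort(config$generator)
  } else if (is.character(config$input)) {
    read_cohort_csv(config$input)
  } else {
    config$input
  }

  violations <- validate_cohort(cohort)
  write_table(violations, out_dir, "validation_violations.csv")

  cohort <- derive_measures(cohort)
  split <- apply_exclusions(cohort)
  analysis <- split$analysis
  write_table(split$exclusions, out_dir, "exclusion_log.csv")

  defs <- mets_definitions()[c("MetS-H", config$definitions)]
  calls <- classify_cohort(analysis, config$thresholds, defs)
  write_table(calls, out_dir, "classification.csv")

  descriptives <- descriptives_table(analysis)
  write_table(descriptives, out_dir, "descriptives.csv")

  criteria_tab <- criteria_by_definition(calls, defs)
  write_table(criteria_tab, out_dir, "criteria_by_definition.csv")

  ref_col <- call_column("MetS-H")
  comparisons <- list()
  accuracy <- list()
  for (def_name in config$definitions) {
    idx_col <- call_column(def_name)
    keep <- calls[[idx_col]] != "indeterminate" &
      calls[[ref_col]] != "indeterminate"
    tab <- cross_tabulate(calls[[idx_col]][keep], calls[[ref_col]][keep],
                          index_name = def_name, reference_name = "MetS-H")
    ds <- diagnostic_summary(tab)
    comparisons[[def_name]] <- data.frame(
      index = def_name, reference = "MetS-H",
      tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
      kappa = ds$kappa$kappa, kappa_lower = ds$kappa$lower,
      kappa_upper = ds$kappa$upper, agreement = ds$agreement_label,
      stringsAsFactors = FALSE
    )
    acc <- cbind(index = def_name, sex = "overall", ds$metrics)
    for (s in c("male", "female")) {
      sel <- keep & analysis$sex == s
      tab_s <- cross_tabulate(calls[[idx_col]][sel], calls[[ref_col]][sel],
                              index_name = def_name, reference_name = "MetS-H")
      acc <- rbind(acc, cbind(index = def_name, sex = s,
                              diagnostic_summary(tab_s)$metrics))
    }
    accuracy[[def_name]] <- acc
  }
  comparisons <- do.call(rbind, comparisons)
  accuracy <- do.call(rbind, accuracy)
  rownames(comparisons) <- rownames(accuracy) <- NULL
  write_table(comparisons, out_dir, "comparisons.csv")
  write_table(accuracy, out_dir, "diagnostic_accuracy.csv")

  prevalence <- prevalence_tables(calls, analysis, defs, config$standard)
  write_table(prevalence, out_dir, "prevalence.csv")

  regression <- regression_tables(calls, analysis)
  write_table(regression, out_dir, "regression.csv")

  provenance <- list(
    package = "metscreen",
    version = as.character(utils::packageVersion("metscreen")),
    thresholds = config$thresholds,
    definitions = names(defs),
    seed = if (!is.null(config$generator)) config$generator$seed else NULL,
    n_input = nrow(cohort), n_analysis = nrow(analysis),
    n_excluded = nrow(split$exclusions)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(descriptives = descriptives, criteria = criteria_tab,
                 comparisons = comparisons, accuracy = accuracy,
                 prevalence = prevalence, regression = regression,
                 exclusions = split$exclusions, violations = violations,
                 calls = calls, provenance = provenance),
            class = "report_bundle")
}

descriptives_table <- function(analysis) {
  n <- nrow(analysis)
  row <- function(characteristic, value) {
    data.frame(characteristic = characteristic, value = value,
               stringsAsFactors = FALSE)
  }
  count_row <- function(characteristic, k) {
    row(characteristic, sprintf("%d (%.1f%%)", k, 100 * k / n))
  }
  band <- age_bands_of(analysis$age)
  out <- rbind(
    row("n", as.character(n)),
    row("age mean (SD)", sprintf("%.1f (%.1f)", mean(analysis$age),
                                 stats::sd(analysis$age))),
    count_row("female", sum(analysis$sex == "female")),
    do.call(rbind, lapply(levels(band), function(b) {
      count_row(paste("age", b), sum(band == b))
    })),
    count_row("education: secondary or higher",
              sum(analysis$education == "secondary_or_higher", na.rm = TRUE)),
    count_row("income: <= $1/day",
              sum(analysis$income_band == "le_1_usd_day", na.rm = TRUE)),
    count_row("income: $1-10/day",
              sum(analysis$income_band == "usd_1_to_10_day", na.rm = TRUE)),
    count_row("income: > $10/day",
              sum(analysis$income_band == "gt_10_usd_day", na.rm = TRUE)),
    count_row("smoking: current/former",
              sum(analysis$smoking == "current_former", na.rm = TRUE)),
    count_row("high alcohol use", sum(analysis$high_alcohol, na.rm = TRUE)),
    count_row("low fruit/vegetable intake",
              sum(analysis$low_fruit_veg, na.rm = TRUE)),
    count_row("physically inactive",
              sum(analysis$physically_inactive, na.rm = TRUE))
  )
  rownames(out) <- NULL
  out
}

criteria_by_definition <- function(calls, defs) {
  groups <- c(list(overall = rep(TRUE, nrow(calls))),
              stats::setNames(lapply(names(defs), function(d) {
                calls[[call_column(d)]] == "positive"
              }), names(defs)))
  out <- data.frame(criterion = criterion_names, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    sel <- groups[[g]]
    out[[paste0(g, "_n")]] <- vapply(criterion_names, function(cr) {
      sum(calls[[cr]][sel], na.rm = TRUE)
    }, numeric(1))
    out[[paste0(g, "_pct")]] <- vapply(criterion_names, function(cr) {
      100 * mean(calls[[cr]][sel], na.rm = TRUE)
    }, numeric(1))
  }
  out
}

prevalence_tables <- function(calls, analysis, defs, standard = NULL) {
  if (is.null(standard)) standard <- who_standard_population()
  out <- list()
  for (d in names(defs)) {
    cc <- calls[[call_column(d)]]
    keep <- cc != "indeterminate"
    est <- crude_prevalence(cc[keep], stratum = "crude")
    by_sex <- stratified_prevalence(cc[keep], analysis$sex[keep])
    band <- age_bands_of(analysis$age[keep])
    by_age <- stratified_prevalence(cc[keep], band)
    std <- age_standardized_prevalence(cc[keep], analysis$age[keep],
                                       standard = standard)
    block <- rbind(est, by_sex, by_age, std)
    block <- cbind(definition = d, block)
    out[[d]] <- block
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

regression_tables <- function(calls, analysis) {
  dat <- analysis
  dat$mets_h <- calls$mets_h[match(dat$id, calls$id)]
  dat <- dat[dat$mets_h != "indeterminate", ]
  dat$age_band <- age_bands_of(dat$age)
  dat$poverty <- ifelse(is.na(dat$income_band), NA_character_,
                        ifelse(dat$income_band == "le_1_usd_day",
                               "le_1_usd_day", "gt_1_usd_day"))
  covs <- c("age_band", "sex", "education", "poverty", "smoking")
  unadj <- fit_prevalence_model(dat, "mets_h", covs, family = "log_binomial",
                                adjusted = FALSE)
  adj <- fit_prevalence_model(dat, "mets_h", covs, family = "log_binomial",
                              adjusted = TRUE)
  sens <- compare_families(dat, "mets_h", covs, adjusted = TRUE)
  out <- merge(
    stats::setNames(unadj$results,
                    c("term", paste0("unadjusted_", names(unadj$results)[-1]))),
    stats::setNames(adj$results,
                    c("term", paste0("adjusted_", names(adj$results)[-1]))),
    by = "term", sort = FALSE
  )
  out <- merge(out, sens[, c("term",
                             "poisson_robust_estimate", "poisson_robust_lower",
                             "poisson_robust_upper", "logistic_estimate",
                             "logistic_lower", "logistic_upper")],
               by = "term", sort = FALSE)
  out
}

#' Replay pre-tabulated 2x2 comparison cells (tables mode)
#'
#' Takes printed comparison-table cells — a CSV path or a list of
#' [confusion_table()] objects — and recomputes the full diagnostic accuracy
#' and agreement analysis plus the crude prevalences implied by the table
#' margins, without any participant-level data.
#'
#' @param cells CSV path (see [read_confusion_cells()]) or list of
#'   [confusion_table()] objects.
#' @param out_dir Optional output directory.
#' @return A list with `summaries` (one [diagnostic_summary()] per
#'   comparison), `accuracy` and `comparisons` data frames, and `prevalence`
#'   (crude index and reference prevalence per comparison).
#' @export
run_tables_report <- function(cells, out_dir = NULL) {
  if (is.character(cells)) cells <- read_confusion_cells(cells)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  summaries <- lapply(cells, diagnostic_summary)
  accuracy <- do.call(rbind, lapply(names(cells), function(nm) {
    cbind(index = nm, summaries[[nm]]$metrics)
  }))
  comparisons <- do.call(rbind, lapply(names(cells), function(nm) {
    tab <- cells[[nm]]
    k <- summaries[[nm]]$kappa
    data.frame(index = nm, reference = tab$reference_name,
               tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
               kappa = k$kappa, kappa_lower = k$lower, kappa_upper = k$upper,
               agreement = summaries[[nm]]$agreement_label,
               stringsAsFactors = FALSE)
  }))
  prevalence <- do.call(rbind, lapply(names(cells), function(nm) {
    tab <- cells[[nm]]
    n <- tab$tp + tab$fp + tab$fn + tab$tn
    idx <- exact_binomial_ci(tab$tp + tab$fp, n)
    ref <- exact_binomial_ci(tab$tp + tab$fn, n)
    data.frame(
      index = nm, reference = tab$reference_name, n = n,
      index_positives = tab$tp + tab$fp,
      index_prevalence = (tab$tp + tab$fp) / n,
      index_lower = idx[["lower"]], index_upper = idx[["upper"]],
      reference_positives = tab$tp + tab$fn,
      reference_prevalence = (tab$tp + tab$fn) / n,
      reference_lower = ref[["lower"]], reference_upper = ref[["upper"]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(accuracy) <- rownames(comparisons) <- rownames(prevalence) <- NULL
  write_table(accuracy, out_dir, "tables_mode_accuracy.csv")
  write_table(comparisons, out_dir, "tables_mode_comparisons.csv")
  write_table(prevalence, out_dir, "tables_mode_prevalence.csv")
  list(summaries = summaries, accuracy = accuracy, comparisons = comparisons,
       prevalence = prevalence)
}
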