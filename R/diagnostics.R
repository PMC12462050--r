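# Diagnostic accuracy of an index screening rule against a reference:
# 2x2 cross-tabulation, exact (Clopper-Pearson) binomial limits for
# sensitivity/specificity/predictive values, and Cohen's kappa.

#' Construct a 2x2 confusion table
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts (index positive &
#'   reference positive, index positive & reference negative, and so on).
#' @param index_name,reference_name Labels for the two classifications.
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn, index_name = "index",
                            reference_name = "reference") {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion table cells must be nonnegative integers")
  }
  if (sum(cells) == 0) stop("confusion table must have a positive total")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 index_name = index_name, reference_name = reference_name),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(paste(x$index_name, c("positive", "negative")),
                              paste(x$reference_name, c("positive", "negative"))))
  print(m)
  invisible(x)
}

#' Cross-tabulate index calls against reference calls
#'
#' @param index_calls,reference_calls Aligned vectors of calls, either logical
#'   or `"positive"`/`"negative"` character. Indeterminate or missing calls
#'   are an error: resolve or drop them first.
#' @param index_name,reference_name Labels.
#' @return A [confusion_table()].
#' @export
cross_tabulate <- function(index_calls, reference_calls,
                           index_name = "index", reference_name = "reference") {
  if (length(index_calls) != length(reference_calls)) {
    stop("index and reference call vectors differ in length")
  }
  idx <- as_call_logical(index_calls, "index")
  ref <- as_call_logical(reference_calls, "reference")
  confusion_table(
    tp = sum(idx & ref), fp = sum(idx & !ref),
    fn = sum(!idx & ref), tn = sum(!idx & !ref),
    index_name = index_name, reference_name = reference_name
  )
}

as_call_logical <- function(calls, what) {
  if (is.character(calls) || is.factor(calls)) {
    calls <- as.character(calls)
    if (any(calls == "indeterminate", na.rm = TRUE)) {
      stop(what, " calls contain indeterminate entries")
    }
    bad <- !calls %in% c("positive", "negative")
    if (any(bad)) stop(what, " calls contain unknown codes")
    calls <- calls == "positive"
  }
  if (any(is.na(calls))) stop(what, " calls contain missing entries")
  as.logical(calls)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Obtained by inverting the binomial tail probabilities via beta quantiles;
#' the lower limit is 0 when no successes are observed and the upper limit 1
#' when all trials succeed.
#'
#' @param successes,n Integer counts, `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level in (0, 1).
#' @return Numeric vector `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  if (n < 1 || successes < 0 || successes > n) {
    stop("need 0 <= successes <= n and n >= 1")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with a large-sample
#' Wald interval using the Fleiss-Cohen-Everitt standard error. In the
#' degenerate case `p_e = 1` (both margins concentrated in one cell) kappa is
#' defined as 1 when observed agreement is perfect and 0 otherwise, and the
#' result is flagged `degenerate`.
#'
#' @param table A [confusion_table()].
#' @param level Confidence level.
#' @return A list with `kappa`, `lower`, `upper`, `se` and `degenerate`.
#' @export
cohens_kappa <- function(table, level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  n <- table$tp + table$fp + table$fn + table$tn
  # cell proportions p[i, j]: index in rows, reference in columns
  p <- matrix(c(table$tp, table$fn, table$fp, table$tn), nrow = 2) / n
  row_m <- rowSums(p)
  col_m <- colSums(p)
  p_o <- sum(diag(p))
  p_e <- sum(row_m * col_m)

  if (1 - p_e < .Machine$double.eps) {
    k <- if (p_o >= 1 - .Machine$double.eps) 1 else 0
    return(list(kappa = k, lower = NA_real_, upper = NA_real_, se = NA_real_,
                degenerate = TRUE))
  }

  kappa <- (p_o - p_e) / (1 - p_e)

  # Fleiss, Cohen & Everitt large-sample variance
  a <- sum(diag(p) * ((1 - p_e) - (row_m + col_m) * (1 - p_o))^2)
  off <- (1 - p_o)^2 * (p[1, 2] * (col_m[1] + row_m[2])^2 +
                          p[2, 1] * (col_m[2] + row_m[1])^2)
  c_term <- (p_o * p_e - 2 * p_e + p_o)^2
  var_k <- (a + off - c_term) / (n * (1 - p_e)^4)
  se <- sqrt(max(var_k, 0))

  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = kappa,
       lower = max(-1, kappa - z * se),
       upper = min(1, kappa + z * se),
       se = se, degenerate = FALSE)
}

#' Qualitative agreement label for a kappa value
#'
#' Landis-Koch bands: poor (below 0), slight (0-0.20], fair (0.21-0.40],
#' moderate (0.41-0.60], substantial (0.61-0.80], almost perfect above 0.80.
#'
#' @param kappa Kappa value in [-1, 1].
#' @return A character label.
#' @export
agreement_label <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Diagnostic accuracy summary for a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(fn+tn)`, each with
#' an exact binomial confidence interval, plus Cohen's kappa with its
#' large-sample interval and qualitative agreement label. A metric whose
#' denominator is zero is reported as missing with an explicit reason.
#'
#' @param table A [confusion_table()].
#' @param level Confidence level.
#' @return A list of class `diagnostic_summary` with elements `metrics`
#'   (data frame: metric, successes, n, estimate, lower, upper, note),
#'   `kappa` (from [cohens_kappa()]), `agreement_label` and `table`.
#' @export
diagnostic_summary <- function(table, level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  spec <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$fp + table$tn),
    ppv = c(table$tp, table$tp + table$fp),
    npv = c(table$tn, table$fn + table$tn)
  )
  rows <- lapply(names(spec), function(metric) {
    x <- spec[[metric]][1]
    n <- spec[[metric]][2]
    if (n == 0) {
      data.frame(metric = metric, successes = NA_integer_, n = 0L,
                 estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                 note = "undefined: zero denominator", stringsAsFactors = FALSE)
    } else {
      ci <- exact_binomial_ci(x, n, level)
      data.frame(metric = metric, successes = x, n = n, estimate = x / n,
                 lower = ci[["lower"]], upper = ci[["upper"]], note = "",
                 stringsAsFactors = FALSE)
    }
  })
  kap <- cohens_kappa(table, level)
  structure(list(metrics = do.call(rbind, rows), kappa = kap,
                 agreement_label = agreement_label(kap$kappa), table = table),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  cat(sprintf("%s vs %s (n = %d)\n", x$table$index_name,
              x$table$reference_name,
              x$table$tp + x$table$fp + x$table$fn + x$table$tn))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-11s %s\n", m$metric[i], m$note[i]))
    } else {
      cat(sprintf("  %-11s %5.1f%% (95%% CI %.1f, %.1f)\n", m$metric[i],
                  100 * m$estimate[i], 100 * m$lower[i], 100 * m$upper[i]))
    }
  }
  if (!is.na(x$kappa$lower)) {
    cat(sprintf("  kappa       %5.1f (95%% CI %.1f, %.1f) - %s\n",
                100 * x$kappa$kappa, 100 * x$kappa$lower, 100 * x$kappa$upper,
                x$agreement_label))
  } else {
    cat(sprintf("  kappa       %5.1f (degenerate margins)\n", 100 * x$kappa$kappa))
  }
  invisible(x)
}

#' Read or write 2x2 cells so printed tables can be replayed directly
#'
#' The CSV has columns `index_name`, `reference_name`, `tp`, `fp`, `fn`,
#' `tn`, one row per comparison.
#'
#' @param path CSV path.
#' @return A list of [confusion_table()] objects, named by `index_name`.
#' @export
read_confusion_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("index_name", "reference_name", "tp", "fp", "fn", "tn")
  if (!all(needed %in% names(df))) {
    stop("cells CSV needs columns: ", paste(needed, collapse = ", "))
  }
  tabs <- lapply(seq_len(nrow(df)), function(i) {
    confusion_table(df$tp[i], df$fp[i], df$fn[i], df$tn[i],
                    index_name = df$index_name[i],
                    reference_name = df$reference_name[i])
  })
  names(tabs) <- df$index_name
  tabs
}
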