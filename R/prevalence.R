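# Crude, stratified and directly age-standardized prevalence.

#' Crude prevalence with exact binomial confidence interval
#'
#' @param calls Logical vector or `"positive"`/`"negative"` character calls;
#'   indeterminate or missing calls are an error.
#' @param level Confidence level.
#' @param stratum Optional stratum label carried into the result.
#' @return A one-row data frame: `stratum`, `positives`, `n`, `point`,
#'   `lower`, `upper`.
#' @export
crude_prevalence <- function(calls, level = 0.95, stratum = NA_character_) {
  if (length(calls) == 0) stop("no calls supplied")
  pos <- as_call_logical(calls, "prevalence")
  x <- sum(pos)
  n <- length(pos)
  ci <- exact_binomial_ci(x, n, level)
  data.frame(stratum = stratum, positives = x, n = n, point = x / n,
             lower = ci[["lower"]], upper = ci[["upper"]],
             stringsAsFactors = FALSE)
}

#' Prevalence stratified by a grouping label
#'
#' @param calls Calls as in [crude_prevalence()].
#' @param strata Vector of stratum labels aligned with `calls`; rows with a
#'   missing label are dropped with a message.
#' @param level Confidence level.
#' @return A data frame with one row per non-empty stratum; stratum `n`s sum
#'   to the number of labelled calls.
#' @export
stratified_prevalence <- function(calls, strata, level = 0.95) {
  if (length(calls) != length(strata)) {
    stop("calls and strata differ in length")
  }
  keep <- !is.na(strata)
  if (any(!keep)) {
    message(sum(!keep), " calls without a stratum label dropped")
  }
  calls <- calls[keep]
  strata <- strata[keep]
  levels <- if (is.factor(strata)) levels(droplevels(strata)) else unique(strata)
  out <- lapply(levels, function(s) {
    crude_prevalence(calls[strata == s], level = level, stratum = as.character(s))
  })
  do.call(rbind, out)
}

#' The WHO 2000-2025 World Standard Population
#'
#' Five-year age-band weights of the WHO World Standard Population, shipped
#' with the package; weights are renormalized to sum to one.
#'
#' @param path Optional path to a user CSV with columns `age_lower`,
#'   `age_upper` (exclusive) and `weight`, overriding the embedded standard.
#' @return A data frame `age_lower`, `age_upper`, `weight`.
#' @export
who_standard_population <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "who_world_standard_2000_2025.csv",
                        package = "metscreen", mustWork = TRUE)
  }
  std <- utils::read.csv(path)
  stopifnot(all(c("age_lower", "age_upper", "weight") %in% names(std)))
  if (any(std$weight <= 0)) stop("standard weights must be positive")
  std$weight <- std$weight / sum(std$weight)
  std[order(std$age_lower), ]
}

#' Default adult age bands
#'
#' The analysis bands: 18-29, 30-39, 40-49, 50-59 and 60 and over, with
#' half-open edges `[lower, upper)`.
#'
#' @return A data frame `label`, `lower`, `upper`.
#' @export
default_age_bands <- function() {
  data.frame(
    label = c("18-29", "30-39", "40-49", "50-59", "60+"),
    lower = c(18, 30, 40, 50, 60),
    upper = c(30, 40, 50, 60, Inf),
    stringsAsFactors = FALSE
  )
}

#' Assign ages to analysis bands
#'
#' @param age Numeric ages.
#' @param bands Band table as from [default_age_bands()].
#' @return A factor of band labels (NA outside all bands).
#' @export
age_bands_of <- function(age, bands = default_age_bands()) {
  out <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(bands))) {
    sel <- !is.na(age) & age >= bands$lower[i] & age < bands$upper[i]
    out[sel] <- bands$label[i]
  }
  factor(out, levels = bands$label)
}

#' Collapse a standard population onto analysis age bands
#'
#' Five-year standard weights are apportioned uniformly by year of age into
#' the target bands (so a band starting at 18 takes 2/5 of the 15-19 weight),
#' then renormalized over the bands so the collapsed weights sum to one.
#'
#' @param standard A standard population from [who_standard_population()].
#' @param bands Target bands from [default_age_bands()].
#' @return A data frame `label`, `lower`, `upper`, `weight`.
#' @export
collapse_standard <- function(standard, bands = default_age_bands()) {
  weight <- numeric(nrow(bands))
  for (i in seq_len(nrow(bands))) {
    lo <- bands$lower[i]
    hi <- bands$upper[i]
    overlap <- pmax(0, pmin(standard$age_upper, hi) - pmax(standard$age_lower, lo))
    weight[i] <- sum(standard$weight * overlap /
                       (standard$age_upper - standard$age_lower))
  }
  if (sum(weight) <= 0) stop("no overlap between standard and target bands")
  out <- bands
  out$weight <- weight / sum(weight)
  out
}

#' Directly age-standardized prevalence
#'
#' Weighted average of band-specific prevalences using a fixed standard
#' population's weights: point estimate `sum(w_b * p_b)`, variance
#' `sum(w_b^2 * p_b (1 - p_b) / n_b)` and a normal-approximation interval
#' truncated to [0, 1].
#'
#' @param band_prevalences Data frame with columns `label`, `positives`, `n`
#'   (`n > 0` for every band).
#' @param standard Collapsed standard with columns `label` and `weight`
#'   (weights renormalized here if needed); every standard band must be
#'   present in the data.
#' @param level Confidence level.
#' @return A one-row data frame: `point`, `lower`, `upper`, `n`, `positives`,
#'   `stratum = "age-standardized"`.
#' @export
direct_standardize <- function(band_prevalences, standard, level = 0.95) {
  stopifnot(all(c("label", "positives", "n") %in% names(band_prevalences)),
            all(c("label", "weight") %in% names(standard)))
  missing_bands <- setdiff(standard$label, band_prevalences$label)
  if (length(missing_bands) > 0) {
    stop("no data for standard band(s): ", paste(missing_bands, collapse = ", "))
  }
  dat <- merge(standard[, c("label", "weight")], band_prevalences, by = "label")
  if (any(dat$n <= 0)) stop("every band needs n > 0")
  dat$weight <- dat$weight / sum(dat$weight)
  p <- dat$positives / dat$n
  point <- sum(dat$weight * p)
  v <- sum(dat$weight^2 * p * (1 - p) / dat$n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(stratum = "age-standardized",
             positives = sum(dat$positives), n = sum(dat$n),
             point = point,
             lower = max(0, point - z * sqrt(v)),
             upper = min(1, point + z * sqrt(v)),
             stringsAsFactors = FALSE)
}

#' Age-standardized prevalence of a call vector
#'
#' Convenience wrapper: tabulates band-specific prevalence from ages, collapses
#' the WHO standard onto the analysis bands and standardizes.
#'
#' @param calls Calls as in [crude_prevalence()].
#' @param age Ages aligned with `calls`.
#' @param bands Analysis bands.
#' @param standard A standard population (5-year bands).
#' @param level Confidence level.
#' @return As [direct_standardize()].
#' @export
age_standardized_prevalence <- function(calls, age,
                                        bands = default_age_bands(),
                                        standard = who_standard_population(),
                                        level = 0.95) {
  pos <- as_call_logical(calls, "prevalence")
  band <- age_bands_of(age, bands)
  if (any(is.na(band))) stop("ages outside the analysis bands")
  tab <- data.frame(label = levels(band),
                    positives = as.integer(tapply(pos, band, sum, default = 0)),
                    n = as.integer(table(band)),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$n > 0, ]
  std <- collapse_standard(standard, bands[bands$label %in% tab$label, ])
  direct_standardize(tab, std, level = level)
}
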