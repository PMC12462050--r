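# Prevalence-ratio regression of a binary call on categorical covariates:
# log-binomial as the primary model, robust (sandwich) Poisson and logistic
# as sensitivity analyses.

#' Default covariate coding for the cohort regression
#'
#' Categorical covariates with their reference levels: age band (reference
#' under 30), sex (reference male), education (reference secondary or
#' higher), income poverty (reference at or below $1/day) and smoking
#' (reference current/former). The design matrix one-hot codes each factor
#' against its reference.
#'
#' @return A named list mapping covariate column name to its level ordering
#'   (reference first).
#' @export
default_covariate_levels <- function() {
  list(
    age_band = c("18-29", "30-39", "40-49", "50-59", "60+"),
    sex = c("male", "female"),
    education = c("secondary_or_higher", "less_than_secondary"),
    income_band = c("le_1_usd_day", "usd_1_to_10_day", "gt_10_usd_day"),
    poverty = c("le_1_usd_day", "gt_1_usd_day"),
    smoking = c("current_former", "never")
  )
}

prepare_model_frame <- function(data, outcome, covariates,
                                levels = default_covariate_levels()) {
  stopifnot(outcome %in% names(data), all(covariates %in% names(data)))
  y <- data[[outcome]]
  if (is.character(y)) y <- y == "positive"
  y <- as.integer(y)
  if (any(!y %in% c(0L, 1L), na.rm = TRUE)) stop("outcome must be binary")
  mf <- data.frame(.y = y)
  for (cov in covariates) {
    v <- data[[cov]]
    if (cov %in% names(levels) && !is.factor(v)) {
      v <- factor(v, levels = levels[[cov]])
    } else if (!is.factor(v)) {
      v <- factor(v)
    }
    mf[[cov]] <- v
  }
  complete <- stats::complete.cases(mf)
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(dropped, " rows with missing outcome or covariates dropped")
  }
  mf[complete, , drop = FALSE]
}

fit_one_family <- function(mf, covariates, family, level = 0.95) {
  form <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  z <- stats::qnorm(1 - (1 - level) / 2)
  convergence <- "converged"

  if (family == "log_binomial") {
    # start the binomial log-link IRLS from the Poisson solution; glm's
    # step-halving then keeps fitted probabilities inside (0, 1)
    pois <- stats::glm(form, data = mf, family = stats::poisson(link = "log"))
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, data = mf,
                                  family = stats::binomial(link = "log"),
                                  start = stats::coef(pois),
                                  control = stats::glm.control(maxit = 200))),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged ||
        any(fit$fitted.values > 1 - 1e-8)) {
      warning("log-binomial fit did not converge; robust Poisson estimates substituted")
      res <- fit_one_family(mf, covariates, "poisson_robust", level)
      res$convergence <- "fallback_used"
      return(res)
    }
    vc <- stats::vcov(fit)
  } else if (family == "poisson_robust") {
    fit <- stats::glm(form, data = mf, family = stats::poisson(link = "log"))
    if (!fit$converged) convergence <- "failed"
    vc <- sandwich::vcovHC(fit, type = "HC0")
  } else if (family == "logistic") {
    fit <- stats::glm(form, data = mf, family = stats::binomial(link = "logit"))
    if (!fit$converged) convergence <- "failed"
    vc <- stats::vcov(fit)
  } else {
    stop("unknown family: ", family)
  }

  beta <- stats::coef(fit)
  se <- sqrt(diag(vc))
  keep <- names(beta) != "(Intercept)"
  est <- data.frame(
    term = names(beta)[keep],
    estimate = exp(beta[keep]),
    lower = exp(beta[keep] - z * se[keep]),
    upper = exp(beta[keep] + z * se[keep]),
    p = 2 * stats::pnorm(-abs(beta[keep] / se[keep])),
    stringsAsFactors = FALSE
  )
  rownames(est) <- NULL
  list(results = est, family = family, convergence = convergence,
       loglik = as.numeric(stats::logLik(fit)), n = nrow(mf), fit = fit)
}

#' Fit a prevalence-ratio (or odds-ratio) model
#'
#' The primary model is the log-binomial GLM, whose exponentiated
#' coefficients are prevalence ratios; `poisson_robust` gives prevalence
#' ratios with sandwich (HC0) standard errors and `logistic` gives odds
#' ratios. Confidence intervals are Wald intervals on the log scale. When
#' the log-binomial likelihood cannot be maximized in the interior
#' (fitted probabilities at the boundary or IRLS divergence) the robust
#' Poisson results are substituted with `convergence = "fallback_used"` and
#' a warning.
#'
#' In adjusted mode all covariates enter one model; in unadjusted mode each
#' covariate is fitted alone and the per-covariate results are stacked.
#'
#' @param data Data frame holding the outcome and covariate columns.
#' @param outcome Name of the binary outcome column (logical, 0/1, or
#'   positive/negative character).
#' @param covariates Character vector of categorical covariate columns.
#' @param family `"log_binomial"`, `"poisson_robust"` or `"logistic"`.
#' @param adjusted Single multivariable model (`TRUE`) or one covariate at a
#'   time (`FALSE`).
#' @param levels Reference-level coding, see [default_covariate_levels()].
#' @param level Confidence level.
#' @return A list with `results` (data frame: term, estimate, lower, upper,
#'   p on the ratio scale), `family`, `convergence`, `loglik` and `n`.
#' @export
fit_prevalence_model <- function(data, outcome, covariates,
                                 family = c("log_binomial", "poisson_robust",
                                            "logistic"),
                                 adjusted = TRUE,
                                 levels = default_covariate_levels(),
                                 level = 0.95) {
  family <- match.arg(family)
  if (adjusted) {
    mf <- prepare_model_frame(data, outcome, covariates, levels)
    res <- fit_one_family(mf, covariates, family, level)
    res$fit <- NULL
    return(res)
  }
  fits <- lapply(covariates, function(cov) {
    mf <- prepare_model_frame(data, outcome, cov, levels)
    fit_one_family(mf, cov, family, level)
  })
  list(results = do.call(rbind, lapply(fits, `[[`, "results")),
       family = family,
       convergence = vapply(fits, `[[`, character(1), "convergence"),
       loglik = vapply(fits, `[[`, numeric(1), "loglik"),
       n = vapply(fits, `[[`, numeric(1), "n"))
}

#' Compare the three model families side by side
#'
#' One row per coefficient with the log-binomial prevalence ratio, the robust
#' Poisson prevalence ratio and the logistic odds ratio, each with its Wald
#' interval.
#'
#' @inheritParams fit_prevalence_model
#' @return A data frame keyed by `term` with estimate/lower/upper columns per
#'   family.
#' @export
compare_families <- function(data, outcome, covariates, adjusted = TRUE,
                             levels = default_covariate_levels(),
                             level = 0.95) {
  fams <- c("log_binomial", "poisson_robust", "logistic")
  fits <- lapply(fams, function(f) {
    fit_prevalence_model(data, outcome, covariates, family = f,
                         adjusted = adjusted, levels = levels, level = level)
  })
  out <- fits[[1]]$results[, "term", drop = FALSE]
  for (i in seq_along(fams)) {
    r <- fits[[i]]$results
    stopifnot(identical(r$term, out$term))
    for (col in c("estimate", "lower", "upper")) {
      out[[paste(fams[i], col, sep = "_")]] <- r[[col]]
    }
  }
  attr(out, "convergence") <- lapply(fits, `[[`, "convergence")
  out
}
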