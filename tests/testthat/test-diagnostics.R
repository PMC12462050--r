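test_that("cross tabulation matches explicit pair counting", {
  set.seed(11)
  idx <- sample(c("positive", "negative"), 20, replace = TRUE)
  ref <- sample(c("positive", "negative"), 20, replace = TRUE)
  tab <- cross_tabulate(idx, ref)
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in 1:20) {
    cell <- if (idx[i] == "positive" && ref[i] == "positive") "tp"
    else if (idx[i] == "positive") "fp"
    else if (ref[i] == "positive") "fn"
    else "tn"
    counts[cell] <- counts[cell] + 1
  }
  expect_equal(c(tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn), counts)
  expect_equal(tab$tp + tab$fp + tab$fn + tab$tn, 20)
})

test_that("cross tabulation rejects misaligned or unresolved calls", {
  expect_error(cross_tabulate(c("positive"), c("positive", "negative")),
               "length")
  expect_error(cross_tabulate(c("positive", "indeterminate"),
                              c("positive", "negative")), "indeterminate")
  expect_error(cross_tabulate(c(TRUE, NA), c(TRUE, FALSE)), "missing")
  ident <- cross_tabulate(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(ident$fp + ident$fn, 0)
})

test_that("exact binomial interval matches inversion of the binomial tails", {
  # independent oracle: solve the tail equations numerically
  oracle <- function(x, n, alpha = 0.05) {
    lower <- if (x == 0) 0 else {
      stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    }
    upper <- if (x == n) 1 else {
      stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    }
    c(lower = lower, upper = upper)
  }
  for (case in list(c(430, 578), c(5, 10), c(1, 30), c(29, 30), c(2721, 3005))) {
    expect_equal(exact_binomial_ci(case[1], case[2]),
                 oracle(case[1], case[2]), tolerance = 1e-8)
  }
})

test_that("exact interval boundary and symmetry conventions hold", {
  expect_equal(exact_binomial_ci(0, 10)[["lower"]], 0)
  expect_equal(exact_binomial_ci(10, 10)[["upper"]], 1)
  ci <- exact_binomial_ci(5, 10)
  expect_equal(ci[["lower"]], 1 - ci[["upper"]])
  expect_true(ci[["lower"]] < 0.5 && ci[["upper"]] > 0.5)
  expect_error(exact_binomial_ci(5, 10, level = 1.2), "level")
  expect_error(exact_binomial_ci(11, 10), "successes")
})

test_that("exact interval coverage is at least nominal for all n up to 30", {
  p_grid <- seq(0.01, 0.99, by = 0.01)
  for (n in 1:30) {
    bounds <- t(vapply(0:n, function(x) exact_binomial_ci(x, n),
                       numeric(2)))
    for (p in p_grid) {
      covered <- bounds[, 1] <= p & p <= bounds[, 2]
      coverage <- sum(stats::dbinom(0:n, n, p)[covered])
      expect_gte(coverage, 0.95)
    }
  }
})

test_that("kappa matches its defining formula and labels agreement", {
  tab <- confusion_table(430, 181, 148, 1962)
  n <- 2721
  p_o <- (430 + 1962) / n
  p_e <- (611 * 578 + 2110 * 2143) / n^2
  k <- cohens_kappa(tab)
  expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))
  expect_equal(agreement_label(k$kappa), "substantial")
  expect_equal(agreement_label(0.5), "moderate")
  expect_equal(agreement_label(0.15), "slight")
  expect_equal(agreement_label(-0.1), "poor")
})

test_that("kappa is zero under marginal independence and one for agreement", {
  # counts exactly proportional to the margins: p_o == p_e
  tab <- confusion_table(tp = 20, fp = 80, fn = 80, tn = 320)
  expect_equal(cohens_kappa(tab)$kappa, 0)
  perfect <- confusion_table(tp = 40, fp = 0, fn = 0, tn = 60)
  expect_equal(cohens_kappa(perfect)$kappa, 1)
  degenerate <- confusion_table(tp = 50, fp = 0, fn = 0, tn = 0)
  k <- cohens_kappa(degenerate)
  expect_true(k$degenerate)
  expect_equal(k$kappa, 1)
})

test_that("kappa is invariant under transposition of index and reference", {
  tab <- confusion_table(375, 241, 203, 1902)
  transposed <- confusion_table(375, 203, 241, 1902)
  expect_equal(cohens_kappa(tab)$kappa, cohens_kappa(transposed)$kappa)
  expect_equal(cohens_kappa(tab)$se, cohens_kappa(transposed)$se)
})

test_that("scaling the table leaves point estimates fixed and narrows CIs", {
  tab <- confusion_table(30, 10, 20, 90)
  big <- confusion_table(300, 100, 200, 900)
  s1 <- diagnostic_summary(tab)
  s2 <- diagnostic_summary(big)
  expect_equal(s2$metrics$estimate, s1$metrics$estimate)
  expect_equal(cohens_kappa(big)$kappa, cohens_kappa(tab)$kappa)
  expect_true(all(s2$metrics$upper - s2$metrics$lower <
                    s1$metrics$upper - s1$metrics$lower))
})

test_that("sensitivity and specificity ignore prevalence; predictive values do not", {
  tab <- confusion_table(30, 10, 20, 90)
  shifted <- confusion_table(30, 50, 20, 450)  # fp, tn scaled by 5
  s1 <- diagnostic_summary(tab)$metrics
  s2 <- diagnostic_summary(shifted)$metrics
  get <- function(s, m) s$estimate[s$metric == m]
  expect_equal(get(s2, "sensitivity"), get(s1, "sensitivity"))
  expect_equal(get(s2, "specificity"), get(s1, "specificity"))
  expect_false(get(s2, "ppv") == get(s1, "ppv"))
  expect_false(get(s2, "npv") == get(s1, "npv"))
})

test_that("summary handles perfect and degenerate tables", {
  perfect <- diagnostic_summary(confusion_table(40, 0, 0, 60))
  expect_equal(perfect$metrics$estimate, rep(1, 4))
  expect_equal(perfect$kappa$kappa, 1)

  no_ref_pos <- diagnostic_summary(confusion_table(0, 10, 0, 90))
  m <- no_ref_pos$metrics
  expect_true(is.na(m$estimate[m$metric == "sensitivity"]))
  expect_match(m$note[m$metric == "sensitivity"], "zero denominator")
  expect_false(is.na(m$estimate[m$metric == "specificity"]))
})

test_that("point estimates always lie inside their intervals", {
  set.seed(3)
  for (i in 1:20) {
    cells <- stats::rpois(4, 30) + 1
    s <- diagnostic_summary(confusion_table(cells[1], cells[2], cells[3],
                                            cells[4]))
    m <- s$metrics
    expect_true(all(m$lower <= m$estimate & m$estimate <= m$upper))
    k <- s$kappa
    expect_true(k$lower <= k$kappa && k$kappa <= k$upper)
  }
})
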