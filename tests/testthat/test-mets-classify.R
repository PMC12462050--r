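test_that("criterion thresholds sit exactly at the harmonized cutoffs", {
  crit <- function(rec) derive_criteria(derive_measures(rec))

  # waist: sex-specific, inclusive at the threshold
  expect_true(crit(make_record(sex = "female", waist_cm = 80))$e_wc)
  expect_false(crit(make_record(sex = "female", waist_cm = 79.9))$e_wc)
  expect_false(crit(make_record(sex = "male", waist_cm = 80))$e_wc)
  expect_true(crit(make_record(sex = "male", waist_cm = 94))$e_wc)

  # blood pressure: either arm of the OR, or treatment
  expect_true(crit(make_record(sbp = c(120, 130, 130)))$e_bp)
  expect_false(crit(make_record(sbp = c(135, 129, 130.5)))$e_bp)  # mean 129.75
  expect_true(crit(make_record(dbp = c(70, 85, 85)))$e_bp)
  expect_true(crit(make_record(on_antihypertensive = TRUE))$e_bp)

  # glucose: fasting 100, nonfasting 200, or treatment
  expect_true(crit(make_record(glucose_mgdl = 100, fasting = TRUE))$e_glu)
  expect_false(crit(make_record(glucose_mgdl = 150, fasting = FALSE))$e_glu)
  expect_true(crit(make_record(glucose_mgdl = 200, fasting = FALSE))$e_glu)
  expect_true(crit(make_record(glucose_mgdl = 80, fasting = TRUE,
                               on_glucose_treatment = TRUE))$e_glu)

  # HDL: strict inequality, sex-specific
  expect_false(crit(make_record(sex = "male", hdl_mgdl = 40))$low_hdl)
  expect_true(crit(make_record(sex = "male", hdl_mgdl = 39.9))$low_hdl)
  expect_true(crit(make_record(sex = "female", hdl_mgdl = 49))$low_hdl)

  # triglycerides
  expect_true(crit(make_record(tg_mgdl = 150))$e_tg)
  expect_false(crit(make_record(tg_mgdl = 149))$e_tg)

  # behaviors
  expect_true(crit(make_record(smoking = "current_former"))$smoke_or_alcohol)
  expect_true(crit(make_record(alcohol_per_week = 6))$smoke_or_alcohol)
  expect_false(crit(make_record())$smoke_or_alcohol)
  expect_true(crit(make_record(fat_intake = "high"))$high_fat)
})

test_that("strict-orientation thresholds reproduce the > reading", {
  thr <- default_thresholds()
  thr$sbp$inclusive <- FALSE
  rec <- derive_measures(make_record(sbp = c(130, 130, 130),
                                     dbp = c(70, 70, 70)))
  expect_false(derive_criteria(rec, thr)$e_bp)
  expect_true(derive_criteria(rec)$e_bp)
})

test_that("unknown sex codes are rejected", {
  rec <- make_record()
  rec$sex <- "other"
  expect_error(derive_criteria(derive_measures(rec)), "unknown sex")
})

test_that("missing inputs give null criteria, treatment flags decide alone", {
  rec <- make_record()
  rec[, c("sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3")] <- NA
  rec$on_antihypertensive <- NA
  crit <- derive_criteria(derive_measures(rec))
  expect_true(is.na(crit$e_bp))

  rec$on_antihypertensive <- TRUE
  expect_true(derive_criteria(derive_measures(rec))$e_bp)

  # normal readings but an unknown treatment flag stay undecided
  rec2 <- make_record()
  rec2$on_tg_treatment <- NA
  expect_true(is.na(derive_criteria(derive_measures(rec2))$e_tg))
})

test_that("classification agrees with brute-force enumeration for every definition", {
  for (def in mets_definitions()) {
    k <- length(def$criteria)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    names(grid) <- def$criteria
    for (i in seq_len(nrow(grid))) {
      profile <- unlist(grid[i, , drop = TRUE])
      expected <- if (sum(profile) >= def$min_count) "positive" else "negative"
      expect_equal(classify(profile, def), expected)
    }
  }
})

test_that("indeterminate exactly when missing criteria could flip the call", {
  def <- mets_definitions()[["MetS-H"]]
  p <- c(e_bp = TRUE, e_wc = TRUE, e_glu = NA, low_hdl = FALSE, e_tg = FALSE)
  expect_equal(classify(p, def), "indeterminate")
  p["e_glu"] <- FALSE
  expect_equal(classify(p, def), "negative")
  p[c("e_glu", "low_hdl")] <- TRUE
  expect_equal(classify(p, def), "positive")
  # positive calls stand even with other criteria missing
  p["e_tg"] <- NA
  expect_equal(classify(p, def), "positive")
})

test_that("classify errors when the definition references absent criteria", {
  expect_error(classify(c(e_bp = TRUE), mets_definitions()[["MetS-1"]]),
               "lacks criteria")
})

test_that("flipping a criterion to true never turns positive into negative", {
  set.seed(42)
  defs <- mets_definitions()
  for (rep in 1:50) {
    profile <- stats::setNames(sample(c(TRUE, FALSE), 9, replace = TRUE),
                               c("e_bp", "e_wc", "e_glu", "low_hdl", "e_tg",
                                 "pmh", "fh", "high_fat", "smoke_or_alcohol"))
    for (def in defs) {
      before <- classify(profile, def)
      for (cr in def$criteria) {
        flipped <- profile
        flipped[cr] <- TRUE
        after <- classify(flipped, def)
        if (before == "positive") expect_equal(after, "positive")
      }
    }
  }
})

test_that("hand-evaluated fixtures classify as expected under all definitions", {
  calls <- classify_cohort(derive_measures(fixture_trio()))
  expect_equal(calls$mets_h, c("positive", "negative", "negative"))
  expect_equal(calls$mets_1, c("positive", "positive", "negative"))
  expect_equal(calls$mets_2, c("positive", "negative", "negative"))
  expect_equal(calls$mets_3, c("positive", "negative", "negative"))

  # MetS-1 positivity implies two of the MetS-2 and MetS-3 criteria are met
  m1 <- calls$mets_1 == "positive"
  expect_true(all(calls$e_bp[m1] & calls$e_wc[m1]))
})

test_that("an empty cohort classifies to an empty table", {
  empty <- derive_measures(fixture_trio()[0, ])
  expect_equal(nrow(classify_cohort(empty)), 0)
})

test_that("threshold configurations survive a JSON round trip", {
  thr <- default_thresholds()
  thr$waist_female$value <- 88
  thr$tg$inclusive <- FALSE
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds(thr, path)
  back <- read_thresholds(path)
  expect_equal(back, thr)
})
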