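test_that("validation flags exactly the fields outside their windows", {
  win <- plausibility_windows()
  # boundary +/- 1 unit enumeration for the closed-interval convention
  cases <- list(
    list(col = "sbp2", field = "sbp"), list(col = "dbp3", field = "dbp"),
    list(col = "waist_cm", field = "waist_cm"),
    list(col = "hdl_mgdl", field = "hdl_mgdl"),
    list(col = "tg_mgdl", field = "tg_mgdl")
  )
  for (case in cases) {
    w <- win[win$field == case$field, ]
    for (delta in c(-1, 0, 1)) {
      for (edge in c(w$lower, w$upper)) {
        if (!is.finite(edge)) next
        rec <- make_record()
        rec[[case$col]] <- edge + delta
        rep <- validate_cohort(rec)
        inside <- edge + delta >= w$lower && edge + delta <= w$upper
        if (inside) {
          expect_equal(nrow(rep), 0)
        } else {
          expect_equal(rep$field, case$col)
          expect_equal(rep$value, edge + delta)
        }
      }
    }
  }
})

test_that("validation catches implausible readings and strict glucose floor", {
  rec <- make_record(sbp = c(310, 120, 118))
  rep <- validate_cohort(rec)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$field, "sbp1")
  expect_equal(rep$lower, 40)
  expect_equal(rep$upper, 300)

  expect_equal(nrow(validate_cohort(make_record())), 0)
  # upper TG boundary is inclusive, glucose must be strictly positive
  expect_equal(nrow(validate_cohort(make_record(tg_mgdl = 1000))), 0)
  expect_equal(validate_cohort(make_record(glucose_mgdl = 0))$field,
               "glucose_mgdl")
  expect_equal(validate_cohort(make_record(age = 17))$field, "age")
})

test_that("non-numeric values in numeric fields are structural errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- make_record()
  rec$waist_cm <- "eighty"
  utils::write.csv(rec, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "non-numeric")
})

test_that("mean BP uses the second and third readings, with fallbacks", {
  d <- derive_measures(make_record(sbp = c(140, 130, 120)))
  expect_equal(d$mean_sbp, 125)
  expect_false(d$bp_fallback)

  expect_equal(derive_measures(make_record(sbp = c(118, 118, 118)))$mean_sbp, 118)
  two <- derive_measures(make_record(sbp = c(140, 130), dbp = c(80, 76)))
  expect_equal(two$mean_sbp, 135)
  expect_equal(two$mean_dbp, 78)
  expect_true(two$bp_fallback)
  one <- derive_measures(make_record(sbp = 144, dbp = 90))
  expect_equal(one$mean_sbp, 144)
  none <- make_record()
  none[, c("sbp1", "sbp2", "sbp3", "dbp1", "dbp2", "dbp3")] <- NA
  expect_true(is.na(derive_measures(none)$mean_sbp))
})

test_that("mean BP ignores the first of three readings and is symmetric in 2/3", {
  base <- derive_measures(make_record(sbp = c(140, 130, 120)))$mean_sbp
  swapped <- derive_measures(make_record(sbp = c(140, 120, 130)))$mean_sbp
  first_changed <- derive_measures(make_record(sbp = c(90, 130, 120)))$mean_sbp
  expect_equal(base, swapped)
  expect_equal(base, first_changed)
})

test_that("behavior categories follow the declared cutoffs", {
  expect_true(derive_measures(make_record(alcohol_per_week = 5))$high_alcohol)
  expect_false(derive_measures(make_record(alcohol_per_week = 4))$high_alcohol)
  expect_true(derive_measures(make_record(fruit_veg_servings_day = 4.9))$low_fruit_veg)
  expect_false(derive_measures(make_record(fruit_veg_servings_day = 5))$low_fruit_veg)
})

test_that("exclusions partition the cohort and log reasons by field", {
  coh <- make_cohort(
    make_record("a"),
    make_record("b", pregnant = TRUE),
    make_record("c", hdl_mgdl = NA),
    make_record("d", pregnant = TRUE, waist_cm = NA)
  )
  coh <- derive_measures(coh)
  out <- apply_exclusions(coh)
  expect_equal(nrow(out$analysis) + nrow(out$exclusions), nrow(coh))
  expect_equal(out$analysis$id, "a")
  expect_equal(out$exclusions$reason[out$exclusions$id == "b"], "pregnant")
  expect_equal(out$exclusions$reason[out$exclusions$id == "c"],
               "missing:hdl_mgdl")
  expect_equal(out$exclusions$reason[out$exclusions$id == "d"],
               "pregnant;missing:waist_cm")
  counts <- exclusion_counts(out$exclusions)
  expect_equal(counts$n[counts$reason == "pregnant"], 2)
})

test_that("a clean cohort passes through exclusions unchanged", {
  coh <- derive_measures(fixture_trio())
  out <- apply_exclusions(coh)
  expect_equal(out$analysis, coh)
  expect_equal(nrow(out$exclusions), 0)
})

test_that("a missing pregnancy flag does not exclude", {
  rec <- derive_measures(make_record("x"))
  rec$pregnant <- NA
  expect_equal(nrow(apply_exclusions(rec)$analysis), 1)
})

test_that("cohort CSV round-trips, including missing values and history OR", {
  coh <- fixture_trio()
  coh$hdl_mgdl[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back, coh)

  # per-condition history columns are ORed into the composite flag
  alt <- fixture_trio()
  alt$pmh_cvd <- NULL
  alt$pmh_hypertension <- c(1, 0, 0)
  alt$pmh_diabetes <- c(0, 0, 0)
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(alt, path2, row.names = FALSE, na = "")
  back2 <- read_cohort_csv(path2)
  expect_equal(back2$pmh_cvd, c(TRUE, FALSE, FALSE))

  # a single lipid-treatment column feeds both lipid criteria flags
  alt2 <- fixture_trio()
  alt2$on_hdl_treatment <- NULL
  alt2$on_tg_treatment <- NULL
  alt2$on_lipid_treatment <- c(1, 0, 0)
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(alt2, path3, row.names = FALSE, na = "")
  back3 <- read_cohort_csv(path3)
  expect_true(back3$on_hdl_treatment[1] && back3$on_tg_treatment[1])
})
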