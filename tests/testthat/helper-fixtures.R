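# In-code fixtures: a record builder with mid-range defaults and a few
# hand-evaluated participants.

make_record <- function(id = "p1", age = 40, sex = "male",
                        sbp = c(120, 118, 122), dbp = c(76, 74, 72),
                        on_antihypertensive = FALSE, waist_cm = 85,
                        glucose_mgdl = 90, fasting = TRUE,
                        on_glucose_treatment = FALSE, hdl_mgdl = 55,
                        on_hdl_treatment = FALSE, tg_mgdl = 100,
                        on_tg_treatment = FALSE, pmh_cvd = FALSE,
                        fh_cvd = FALSE, smoking = "never",
                        alcohol_per_week = 0, fruit_veg_servings_day = 2,
                        fat_intake = "low", physically_inactive = FALSE,
                        pregnant = FALSE, education = "secondary_or_higher",
                        income_band = "usd_1_to_10_day") {
  sbp <- c(sbp, rep(NA, 3 - length(sbp)))
  dbp <- c(dbp, rep(NA, 3 - length(dbp)))
  data.frame(
    id = id, age = age, sex = sex, education = education,
    income_band = income_band,
    sbp1 = sbp[1], sbp2 = sbp[2], sbp3 = sbp[3],
    dbp1 = dbp[1], dbp2 = dbp[2], dbp3 = dbp[3],
    on_antihypertensive = on_antihypertensive, waist_cm = waist_cm,
    glucose_mgdl = glucose_mgdl, fasting = fasting,
    on_glucose_treatment = on_glucose_treatment, hdl_mgdl = hdl_mgdl,
    on_hdl_treatment = on_hdl_treatment, tg_mgdl = tg_mgdl,
    on_tg_treatment = on_tg_treatment, pmh_cvd = pmh_cvd, fh_cvd = fh_cvd,
    smoking = smoking, alcohol_per_week = alcohol_per_week,
    fruit_veg_servings_day = fruit_veg_servings_day, fat_intake = fat_intake,
    physically_inactive = physically_inactive, pregnant = pregnant,
    stringsAsFactors = FALSE
  )
}

make_cohort <- function(...) {
  do.call(rbind, list(...))
}

# Three hand-evaluated participants used across tests:
# - f_all: female meeting every criterion -> positive under all definitions
# - m_bp_wc: male with only elevated BP and waist -> MetS-1 positive,
#   MetS-H/2/3 negative
# - f_none: female with everything normal -> negative everywhere
fixture_trio <- function() {
  make_cohort(
    make_record("f_all", age = 55, sex = "female",
                sbp = c(150, 145, 149), dbp = c(95, 92, 90),
                waist_cm = 98, glucose_mgdl = 130, hdl_mgdl = 38,
                tg_mgdl = 210, pmh_cvd = TRUE, fh_cvd = TRUE,
                smoking = "current_former", alcohol_per_week = 7,
                fat_intake = "high"),
    make_record("m_bp_wc", age = 45, sex = "male",
                sbp = c(142, 138, 136), dbp = c(88, 86, 84),
                waist_cm = 101, glucose_mgdl = 88, hdl_mgdl = 52,
                tg_mgdl = 95),
    make_record("f_none", age = 30, sex = "female",
                sbp = c(110, 108, 112), dbp = c(70, 68, 72),
                waist_cm = 75, glucose_mgdl = 85, hdl_mgdl = 60,
                tg_mgdl = 80)
  )
}

# Published pairwise comparison cells of the urban Haitian cohort (index
# definition against the laboratory-based reference), shipped as extdata.
published_cells <- function() {
  read_confusion_cells(system.file("extdata",
                                   "haiti_cohort_comparison_cells.csv",
                                   package = "metscreen"))
}
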