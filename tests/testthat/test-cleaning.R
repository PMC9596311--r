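make_raw <- function(n = 1, ...) {
  base <- tibble::tibble(
    pid = paste0("p", seq_len(n)), country = "X", sex = "female", age = 45,
    sbp1 = 122, sbp2 = 120, sbp3 = 118, dbp1 = 82, dbp2 = 80, dbp3 = 78,
    height = 1.60, weight_kg = 60, waist = 80, fpg = 95, total_chol = 180,
    hdl = 50, self_reported_diabetes = FALSE, on_bp_treatment = FALSE,
    smoker = FALSE, pregnant = FALSE, cvd_history = FALSE,
    education_raw = 3, marital_raw = 2, work_raw = 1
  )
  out <- base[rep(1, n), ]
  out$pid <- paste0("p", seq_len(n))
  overrides <- list(...)
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  out
}

test_that("derived measures follow the survey protocol definitions", {
  d <- derive_measures(make_raw(sbp2 = 130, sbp3 = 120, dbp2 = 90, dbp3 = 70))
  expect_equal(d$sbp, 125)  # mean of 2nd and 3rd; 1st discarded
  expect_equal(d$dbp, 80)
  expect_equal(d$bmi, 60 / 1.60^2)

  expect_true(derive_measures(make_raw(fpg = 130))$diabetes)
  expect_true(derive_measures(make_raw(self_reported_diabetes = TRUE))$diabetes)
  expect_false(derive_measures(make_raw(fpg = 125.9))$diabetes)

  expect_false(derive_measures(make_raw(total_chol = 199.9))$high_cholesterol)
  expect_true(derive_measures(make_raw(total_chol = 200))$high_cholesterol)

  expect_true(derive_measures(make_raw(waist = 88))$abdominal_obesity)
  expect_false(derive_measures(make_raw(waist = 87.9))$abdominal_obesity)
  expect_false(derive_measures(make_raw(sex = "male", waist = 101))$abdominal_obesity)
  expect_true(derive_measures(make_raw(sex = "male", waist = 102))$abdominal_obesity)
})

test_that("survey codes collapse to the harmonized categories", {
  expect_equal(as.character(harmonize_education(1:7)),
               c("none", "primary", "primary", "secondary", "secondary",
                 "university", "university"))
  expect_equal(as.character(harmonize_marital(1:6)),
               c("never_married", "married_cohab", rep("div_sep_wid", 3),
                 "married_cohab"))
  expect_equal(as.character(harmonize_work(1:9)),
               c(rep("employed_paid", 3), "employed_unpaid", "student",
                 "homemaker", rep("unemployed", 3)))
})

test_that("records violating each rule are dropped with its reason code", {
  cases <- list(
    list(make_raw(age = 75), "age_window"),
    list(make_raw(age = 29), "age_window"),
    list(make_raw(pregnant = TRUE), "pregnant"),
    list(make_raw(cvd_history = TRUE), "cvd_history"),
    list(make_raw(sbp2 = 65, sbp3 = 65), "sbp_implausible"),
    list(make_raw(sbp2 = 275, sbp3 = 275), "sbp_implausible"),
    list(make_raw(dbp2 = 20, dbp3 = 20), "dbp_implausible"),
    list(make_raw(height = 0.9), "height_implausible"),
    list(make_raw(weight_kg = 310), "weight_implausible"),
    list(make_raw(height = 1.0, weight_kg = 85), "bmi_implausible"),
    list(make_raw(waist = 210), "waist_implausible"),
    list(make_raw(fpg = 44), "fpg_implausible"),
    list(make_raw(total_chol = 800), "chol_implausible"),
    list(make_raw(smoker = NA), "incomplete"),
    list(make_raw(sbp2 = NA), "incomplete")
  )
  for (case in cases) {
    res <- clean_records(case[[1]])
    expect_equal(res$drops$reason, case[[2]])
  }
  # fully valid record is kept
  expect_equal(nrow(clean_records(make_raw())$drops), 0)
})

test_that("the first failing rule in documented order wins", {
  # pregnant AND implausible SBP: pregnancy is checked first
  r <- make_raw(pregnant = TRUE, sbp2 = 60, sbp3 = 60)
  expect_equal(clean_records(r)$drops$reason, "pregnant")
  # implausible SBP AND missing smoker: plausibility precedes complete-case
  r2 <- make_raw(sbp2 = 300, sbp3 = 300, smoker = NA)
  expect_equal(clean_records(r2)$drops$reason, "sbp_implausible")
  expect_equal(drop_reason_order()[1], "age_window")
})

test_that("cleaning is idempotent and conserves record counts", {
  set.seed(5)
  sim <- simulate_country(country_sim_params(n_records = 800), 99)
  res <- clean_records(sim$records)
  expect_equal(nrow(res$clean) + nrow(res$drops), nrow(sim$records))
  # cleaning already-clean data drops nothing
  res2 <- clean_records(res$clean)
  expect_equal(nrow(res2$drops), 0)
  expect_equal(nrow(res2$clean), nrow(res$clean))
})

test_that("the flow table conserves counts per country", {
  raw <- dplyr::bind_rows(
    make_raw(5),
    make_raw(2, age = 80),
    make_raw(1, sbp2 = 60, sbp3 = 60)
  )
  raw$pid <- paste0("p", seq_len(nrow(raw)))
  res <- clean_records(raw)
  flow <- cleaning_report(res$decisions)
  expect_equal(flow$initial, 8)
  expect_equal(flow$after_age_window, 6)
  expect_equal(flow$after_plausibility, 5)
  expect_equal(flow$kept, 5)
  expect_equal(sum(!res$decisions$keep), 3)

  # degenerate: empty input gives an empty report
  empty <- clean_records(make_raw(0))
  expect_equal(nrow(cleaning_report(empty$decisions)), 0)
})

test_that("no derived field survives from an implausible source value", {
  r <- make_raw(fpg = 600)  # implausible glucose would flip diabetes
  res <- clean_records(r)
  expect_equal(nrow(res$clean), 0)
  expect_equal(res$drops$reason, "fpg_implausible")
})
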