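#' Plausibility ranges for measured risk factors
#'
#' @param path Optional path to an alternative YAML range file.
#' @return Named list of `c(lo, hi)` ranges for `sbp`, `dbp`, `height`,
#'   `weight_kg`, `bmi`, `waist`, `fpg`, `total_chol`.
#' @export
plausibility_ranges <- function(path = system.file("extdata",
                                                   "plausibility_ranges.yaml",
                                                   package = "heartage")) {
  rg <- yaml::read_yaml(path)
  lapply(rg, as.numeric)
}

## harmonization of survey codes to analysis categories
.edu_map <- c("1" = "none", "2" = "primary", "3" = "primary",
              "4" = "secondary", "5" = "secondary",
              "6" = "university", "7" = "university")
.marital_map <- c("1" = "never_married", "2" = "married_cohab",
                  "3" = "div_sep_wid", "4" = "div_sep_wid",
                  "5" = "div_sep_wid", "6" = "married_cohab")
.work_map <- c("1" = "employed_paid", "2" = "employed_paid",
               "3" = "employed_paid", "4" = "employed_unpaid",
               "5" = "student", "6" = "homemaker",
               "7" = "unemployed", "8" = "unemployed", "9" = "unemployed")

.harmonize <- function(code, map, levels) {
  factor(unname(map[as.character(code)]), levels = levels)
}

#' Harmonized education, marital and work categories
#'
#' Collapses the survey instrument codes to the analysis categories:
#' education 7 codes to 4 (none / primary / secondary / university), marital
#' status 6 codes to 3 (never married / married or cohabiting / divorced,
#' separated or widowed), work status 9 codes to 5 (employed paid / employed
#' unpaid / student / homemaker / unemployed, which absorbs retirees).
#'
#' @param education_raw,marital_raw,work_raw Integer survey codes.
#' @name harmonize
#' @return Factors at the harmonized levels (NA for unknown codes).
NULL

#' @rdname harmonize
#' @export
harmonize_education <- function(education_raw) {
  .harmonize(education_raw, .edu_map,
             c("none", "primary", "secondary", "university"))
}

#' @rdname harmonize
#' @export
harmonize_marital <- function(marital_raw) {
  .harmonize(marital_raw, .marital_map,
             c("never_married", "married_cohab", "div_sep_wid"))
}

#' @rdname harmonize
#' @export
harmonize_work <- function(work_raw) {
  .harmonize(work_raw, .work_map,
             c("unemployed", "employed_paid", "employed_unpaid",
               "student", "homemaker"))
}

#' Derive analysis measures from raw survey fields
#'
#' SBP and DBP are the mean of the second and third measurements (the first is
#' discarded per protocol); BMI is weight over height squared; diabetes is
#' fasting plasma glucose >= 126 mg/dl or a self-reported diagnosis; high
#' cholesterol is total cholesterol >= 200 mg/dl; abdominal obesity is waist
#' >= 102 cm in men and >= 88 cm in women. Survey codes are harmonized to the
#' 4/3/5-level analysis categories.
#'
#' @param raw Data frame of raw records (see the column dictionary in the
#'   package vignette).
#' @return `raw` with derived columns `sbp`, `dbp`, `bmi`, `diabetes`,
#'   `high_cholesterol`, `abdominal_obesity`, `education4`, `marital3`,
#'   `work5` appended.
#' @export
derive_measures <- function(raw) {
  raw$sbp <- (raw$sbp2 + raw$sbp3) / 2
  raw$dbp <- (raw$dbp2 + raw$dbp3) / 2
  raw$bmi <- raw$weight_kg / raw$height^2
  raw$diabetes <- (!is.na(raw$fpg) & raw$fpg >= 126) |
    (!is.na(raw$self_reported_diabetes) & raw$self_reported_diabetes)
  raw$diabetes[is.na(raw$fpg) & is.na(raw$self_reported_diabetes)] <- NA
  raw$high_cholesterol <- raw$total_chol >= 200
  raw$abdominal_obesity <- ifelse(raw$sex == "male",
                                  raw$waist >= 102, raw$waist >= 88)
  raw$education4 <- harmonize_education(raw$education_raw)
  raw$marital3 <- harmonize_marital(raw$marital_raw)
  raw$work5 <- harmonize_work(raw$work_raw)
  raw
}

## exclusion rules in their fixed, documented order; each record is tagged
## with the FIRST failing rule
.drop_reasons <- c("age_window", "pregnant", "cvd_history",
                   "sbp_implausible", "dbp_implausible", "height_implausible",
                   "weight_implausible", "bmi_implausible", "waist_implausible",
                   "fpg_implausible", "chol_implausible", "incomplete")

#' Drop-reason codes in evaluation order
#' @return Character vector of reason codes.
#' @export
drop_reason_order <- function() .drop_reasons

.outside <- function(x, range) !is.na(x) & (x < range[1] | x > range[2])

#' Population selection and plausibility filtering
#'
#' Applies the inclusion rules — age 30--74, non-pregnant, no self-reported
#' CVD history — and then the plausibility ranges on the derived measures
#' (BP evaluated on the 2nd/3rd-measurement mean), finally excluding records
#' with any missing analysis variable (complete-case). Decisions, not
#' exceptions: every record receives keep/drop with the first failing rule.
#'
#' @param raw Data frame of raw records.
#' @param ranges Plausibility ranges, see [plausibility_ranges()].
#' @return List with `clean` (derived, kept records), `drops` (tibble of
#'   dropped record ids with `reason`), and `decisions` (per-record tibble of
#'   `keep` and `reason`, in input order).
#' @export
clean_records <- function(raw, ranges = plausibility_ranges()) {
  d <- derive_measures(raw)
  n <- nrow(d)
  reason <- rep(NA_character_, n)
  flag <- function(cond, code) {
    reason[is.na(reason) & cond & !is.na(cond)] <<- code
  }
  flag(is.na(d$age) | d$age < 30 | d$age > 74, "age_window")
  flag(!is.na(d$pregnant) & d$pregnant, "pregnant")
  flag(!is.na(d$cvd_history) & d$cvd_history, "cvd_history")
  flag(.outside(d$sbp, ranges$sbp), "sbp_implausible")
  flag(.outside(d$dbp, ranges$dbp), "dbp_implausible")
  flag(.outside(d$height, ranges$height), "height_implausible")
  flag(.outside(d$weight_kg, ranges$weight_kg), "weight_implausible")
  flag(.outside(d$bmi, ranges$bmi), "bmi_implausible")
  flag(.outside(d$waist, ranges$waist), "waist_implausible")
  flag(.outside(d$fpg, ranges$fpg), "fpg_implausible")
  flag(.outside(d$total_chol, ranges$total_chol), "chol_implausible")
  ## complete-case on the variables every analysis stage needs; covariates
  ## used only by the regressions (education etc.) do not exclude here
  analysis_vars <- c("sex", "age", "sbp", "dbp", "bmi", "waist", "fpg",
                     "total_chol", "smoker", "on_bp_treatment", "diabetes",
                     "cvd_history")
  incomplete <- Reduce(`|`, lapply(d[analysis_vars], is.na))
  flag(incomplete, "incomplete")
  keep <- is.na(reason)
  decisions <- tibble::tibble(
    row = seq_len(n),
    pid = if ("pid" %in% names(d)) d$pid else seq_len(n),
    country = if ("country" %in% names(d)) d$country else NA_character_,
    keep = keep,
    reason = reason
  )
  list(
    clean = d[keep, , drop = FALSE],
    drops = decisions[!keep, c("row", "pid", "country", "reason")],
    decisions = decisions
  )
}

#' Per-country cleaning flow table
#'
#' Sequential counts per country: initial records, then remaining after the
#' age window, pregnancy, CVD-history, plausibility, and complete-case steps.
#' Counts are conserved: kept plus all drops equals initial.
#'
#' @param decisions The `decisions` element returned by [clean_records()].
#' @return Tibble with one row per country and one column per step.
#' @export
cleaning_report <- function(decisions) {
  plaus <- grep("_implausible$", .drop_reasons, value = TRUE)
  step_of <- function(reason) {
    ifelse(is.na(reason), NA_character_,
    ifelse(reason == "age_window", "age_window",
    ifelse(reason == "pregnant", "pregnant",
    ifelse(reason == "cvd_history", "cvd_history",
    ifelse(reason %in% plaus, "plausibility", "complete_case")))))
  }
  decisions$step <- step_of(decisions$reason)
  cty_key <- ifelse(is.na(decisions$country), "all", decisions$country)
  by_country <- split(decisions, cty_key)
  rows <- lapply(names(by_country), function(cty) {
    dd <- by_country[[cty]]
    n0 <- nrow(dd)
    drops <- table(factor(dd$step, levels = c("age_window", "pregnant",
                                              "cvd_history", "plausibility",
                                              "complete_case")))
    after <- n0 - cumsum(as.numeric(drops))
    tibble::tibble(
      country = cty, initial = n0,
      after_age_window = after[1], after_pregnancy = after[2],
      after_cvd_history = after[3], after_plausibility = after[4],
      after_complete_case = after[5], kept = sum(dd$keep)
    )
  })
  dplyr::bind_rows(rows)
}
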