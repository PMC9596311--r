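#' Predicted heart age (continuous)
#'
#' Inverts the risk equation: a subject's heart age is the unique age at which
#' a person with all modifiable risk factors at the ideal reference (SBP 125
#' mmHg untreated, BMI 22.5 kg/m^2 — plus total cholesterol 180 and HDL 45
#' mg/dl under the lab variant — non-smoker, non-diabetic) attains the same
#' linear predictor, hence the same 10-year risk. Because only the age term is
#' free on the ideal side, the inversion is closed-form:
#' \deqn{a^* = \exp\{(LP_{subject} - C_{ideal}) / w_{\ln age}\}}
#' with \eqn{C_{ideal}} the sum of the non-age ideal-reference terms.
#'
#' @inheritParams fram_linear_predictor
#' @return Numeric vector of continuous predicted heart ages (years),
#'   pre-censoring.
#' @examples
#' p <- data.frame(sex = "male", age = 50, sbp = 125, on_bp_treatment = FALSE,
#'                 bmi = 22.5, smoker = FALSE, diabetes = FALSE)
#' heart_age(p)  # ideal profile: heart age equals chronological age
#' @export
heart_age <- function(profiles, variant = c("non_lab", "lab")) {
  variant <- match.arg(variant)
  lp <- fram_linear_predictor(profiles, variant)
  pha <- numeric(length(lp))
  for (s in c("male", "female")) {
    idx <- profiles$sex == s
    if (!any(idx)) next
    cs <- fram_coefficients(variant, s)
    w <- cs$weights
    if (w[["ln_age"]] <= 0) stop("configuration error: ln_age weight <= 0")
    c_ideal <- w[["ln_sbp_untreated"]] * log(cs$ideal$sbp) +
      if (variant == "non_lab") {
        w[["ln_bmi"]] * log(cs$ideal$bmi)
      } else {
        w[["ln_total_chol"]] * log(cs$ideal$total_chol) +
          w[["ln_hdl"]] * log(cs$ideal$hdl)
      }
    pha[idx] <- exp((lp[idx] - c_ideal) / w[["ln_age"]])
  }
  pha
}

.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Censor-code a continuous predicted heart age
#'
#' Rounds to the nearest integer year (halves away from zero), then codes
#' values below 30 as `"<30"` and above 80 as `">80"`; in-range values are
#' returned as the integer written in decimal. Censoring is applied after
#' rounding, so 29.6 codes as `"30"`, not `"<30"`.
#'
#' @param pha_continuous Numeric vector of continuous heart ages (finite,
#'   positive).
#' @return Character vector: `"<30"`, `">80"`, or an integer year.
#' @export
censor_code <- function(pha_continuous) {
  if (any(!is.finite(pha_continuous)) || any(pha_continuous <= 0)) {
    stop("censor_code: heart age must be finite and positive")
  }
  r <- .round_half_up(pha_continuous)
  out <- as.character(as.integer(r))
  out[r < 30] <- "<30"
  out[r > 80] <- ">80"
  out
}

#' Numeric view of a coded heart age
#'
#' @param coded Character vector as produced by [censor_code()].
#' @return Integer vector with `NA` at the censored sentinels.
#' @export
pha_coded_numeric <- function(coded) {
  suppressWarnings(as.integer(coded))
}

#' Classify the gap between predicted heart age and chronological age
#'
#' For a numeric coded PHA the gap is `coded - age`: `low` if negative,
#' `equal` if zero, `high` for 1--4 years, `very_high` for 5+ years. The
#' censored sentinels are classified by bounding the gap rather than imputing
#' a number: `">80"` implies a gap of at least `81 - age`, hence `very_high`
#' for every eligible age (<= 74); `"<30"` implies a gap of at most
#' `29 - age`, hence `low`.
#'
#' @param age Chronological age in completed years (30--74).
#' @param coded_pha Coded PHA from [censor_code()].
#' @return Factor with levels `low`, `equal`, `high`, `very_high`.
#' @export
classify_gap <- function(age, coded_pha) {
  stopifnot(all(age >= 30), all(age <= 74))
  num <- pha_coded_numeric(coded_pha)
  gap <- ifelse(coded_pha == ">80", 81 - age,
         ifelse(coded_pha == "<30", 29 - age, num - age))
  cls <- ifelse(gap < 0, "low",
         ifelse(gap == 0, "equal",
         ifelse(gap <= 4, "high", "very_high")))
  factor(cls, levels = c("low", "equal", "high", "very_high"))
}

#' Excess predicted heart age indicator
#'
#' TRUE when the PHA exceeds chronological age by at least one year, i.e. the
#' gap class is `high` or `very_high`.
#'
#' @param gap_class Factor from [classify_gap()].
#' @return Logical vector.
#' @export
excess_pha <- function(gap_class) {
  gap_class %in% c("high", "very_high")
}

#' Lower bound on the PHA - age gap, sentinel-aware
#'
#' Used for the graded excess thresholds (gap >= 5, 10, 20 years): the
#' sentinel `">80"` contributes its bound `81 - age`, and `"<30"` its bound
#' `29 - age`, so threshold comparisons never impute a numeric PHA.
#'
#' @inheritParams classify_gap
#' @return Numeric vector of gap lower bounds (years).
#' @export
pha_gap_lower_bound <- function(age, coded_pha) {
  num <- pha_coded_numeric(coded_pha)
  ifelse(coded_pha == ">80", 81 - age,
  ifelse(coded_pha == "<30", 29 - age, num - age))
}

#' 5-year age band for chronological or predicted heart age
#'
#' Bands run 30-34, 35-39, ..., 75-79, with terminal bands `"<30"` and
#' `">=80"`. Accepts numeric ages or coded PHAs (sentinels map to the
#' terminal bands).
#'
#' @param value Numeric ages or character coded PHAs.
#' @return Factor of band labels ordered from `"<30"` to `">=80"`.
#' @export
pha_age_group <- function(value) {
  levels <- c("<30", paste(seq(30, 75, 5), seq(34, 79, 5), sep = "-"), ">=80")
  if (is.character(value)) {
    num <- pha_coded_numeric(value)
    lab <- ifelse(value == "<30", "<30",
           ifelse(value == ">80", ">=80", NA))
  } else {
    num <- value
    lab <- rep(NA_character_, length(value))
  }
  idx <- is.na(lab)
  band_lo <- 5 * floor(num[idx] / 5)
  lab[idx] <- ifelse(num[idx] < 30, "<30",
              ifelse(num[idx] >= 80, ">=80",
                     paste(band_lo, band_lo + 4, sep = "-")))
  factor(lab, levels = levels)
}

#' Score profiles end to end: risk, heart age, censoring, gap class
#'
#' Convenience wrapper chaining [clamp_calculator_inputs()], [fram_risk()],
#' [heart_age()], [censor_code()] and [classify_gap()].
#'
#' @inheritParams fram_linear_predictor
#' @return `profiles` with columns `clamped`, `linear_predictor`, `risk_10y`,
#'   `pha_continuous`, `pha_coded`, `gap_class`, `excess` appended.
#' @export
score_heart_age <- function(profiles, variant = c("non_lab", "lab")) {
  variant <- match.arg(variant)
  scored <- clamp_calculator_inputs(profiles, variant)
  scored <- fram_risk(scored, variant)
  scored$pha_continuous <- heart_age(scored, variant)
  scored$pha_coded <- censor_code(scored$pha_continuous)
  scored$gap_class <- classify_gap(scored$age, scored$pha_coded)
  scored$excess <- excess_pha(scored$gap_class)
  scored
}
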