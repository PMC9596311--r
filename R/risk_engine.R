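#' Clamp risk-calculator inputs to the ranges the equations accept
#'
#' The Framingham general-CVD calculator accepts SBP in 90--200 mmHg and BMI
#' in 15--50 kg/m^2; values outside those ranges are rounded to the nearest
#' boundary before scoring (distinct from the plausibility filter, which drops
#' records outright). A flag records whether any clamping occurred.
#'
#' @param profiles Data frame with at least `sbp`; `bmi` is required for the
#'   non-laboratory variant.
#' @param variant Which variant the profiles will be scored under; governs
#'   whether `bmi` is required.
#' @return `profiles` with `sbp`/`bmi` clamped and a logical `clamped` column.
#' @export
clamp_calculator_inputs <- function(profiles, variant = c("non_lab", "lab")) {
  variant <- match.arg(variant)
  if (!"sbp" %in% names(profiles) || anyNA(profiles$sbp)) {
    stop("clamp_calculator_inputs: missing values in required field 'sbp'")
  }
  if (variant == "non_lab" &&
      (!"bmi" %in% names(profiles) || anyNA(profiles$bmi))) {
    stop("clamp_calculator_inputs: missing values in required field 'bmi'")
  }
  sbp_new <- pmin(pmax(profiles$sbp, 90), 200)
  clamped <- sbp_new != profiles$sbp
  profiles$sbp <- sbp_new
  if ("bmi" %in% names(profiles) && !anyNA(profiles$bmi)) {
    bmi_new <- pmin(pmax(profiles$bmi, 15), 50)
    clamped <- clamped | (bmi_new != profiles$bmi)
    profiles$bmi <- bmi_new
  }
  profiles$clamped <- clamped
  profiles
}

.check_profiles <- function(profiles, variant, check_age = TRUE) {
  need <- c("sex", "age", "sbp", "on_bp_treatment", "smoker", "diabetes",
            if (variant == "non_lab") "bmi" else c("total_chol", "hdl"))
  missing_cols <- setdiff(need, names(profiles))
  if (length(missing_cols) > 0) {
    stop("profiles missing required fields: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(profiles$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (check_age && any(profiles$age < 30 | profiles$age > 74)) {
    stop("age outside the supported range 30-74 years")
  }
  invisible(profiles)
}

#' Framingham linear predictor
#'
#' Sum over model terms of coefficient times transformed predictor: natural
#' logs of age, SBP (treated or untreated weight chosen per subject), and BMI
#' (non-lab) or total and HDL cholesterol (lab); 0/1 indicators for current
#' smoking and diabetes. Coefficients are sex-specific.
#'
#' @param profiles Data frame of clamped risk profiles (columns `sex`, `age`,
#'   `sbp`, `on_bp_treatment`, `smoker`, `diabetes`, plus `bmi` or
#'   `total_chol` + `hdl`).
#' @param variant `"non_lab"` or `"lab"`.
#' @param check_age Enforce the 30--74 year domain (disable only for internal
#'   inversion diagnostics).
#' @return Numeric vector of linear predictors.
#' @export
fram_linear_predictor <- function(profiles, variant = c("non_lab", "lab"),
                                  check_age = TRUE) {
  variant <- match.arg(variant)
  .check_profiles(profiles, variant, check_age)
  lp <- numeric(nrow(profiles))
  for (s in c("male", "female")) {
    idx <- profiles$sex == s
    if (!any(idx)) next
    w <- fram_coefficients(variant, s)$weights
    p <- profiles[idx, , drop = FALSE]
    w_sbp <- ifelse(p$on_bp_treatment, w[["ln_sbp_treated"]],
                    w[["ln_sbp_untreated"]])
    lp_s <- w[["ln_age"]] * log(p$age) +
      w_sbp * log(p$sbp) +
      w[["smoker"]] * as.numeric(p$smoker) +
      w[["diabetes"]] * as.numeric(p$diabetes)
    lp_s <- lp_s + if (variant == "non_lab") {
      w[["ln_bmi"]] * log(p$bmi)
    } else {
      w[["ln_total_chol"]] * log(p$total_chol) + w[["ln_hdl"]] * log(p$hdl)
    }
    lp[idx] <- lp_s
  }
  lp
}

#' Framingham 10-year general-CVD risk
#'
#' Computes `risk = 1 - S0 ^ exp(LP - mean_LP)` on the probability scale,
#' where `S0` is the sex- and variant-specific 10-year baseline survival and
#' `mean_LP` the cohort mean linear predictor. Risk is carried as a fraction
#' in (0,1); format as percent only when reporting.
#'
#' @inheritParams fram_linear_predictor
#' @return Data frame `profiles` with `linear_predictor` and `risk_10y`
#'   columns appended.
#' @examples
#' p <- data.frame(sex = "female", age = 61, sbp = 140, on_bp_treatment = TRUE,
#'                 bmi = 28, smoker = TRUE, diabetes = FALSE)
#' fram_risk(p)$risk_10y
#' @export
fram_risk <- function(profiles, variant = c("non_lab", "lab"),
                      check_age = TRUE) {
  variant <- match.arg(variant)
  lp <- fram_linear_predictor(profiles, variant, check_age = check_age)
  risk <- numeric(length(lp))
  for (s in c("male", "female")) {
    idx <- profiles$sex == s
    if (!any(idx)) next
    cs <- fram_coefficients(variant, s)
    risk[idx] <- 1 - cs$baseline_survival_10y ^
      exp(lp[idx] - cs$mean_linear_predictor)
  }
  profiles$linear_predictor <- lp
  profiles$risk_10y <- risk
  profiles
}

#' Paired comparison of laboratory vs non-laboratory results
#'
#' Paired t-test on element-wise differences (lab minus non-lab), used for the
#' sensitivity comparison of risks or heart ages computed under both model
#' variants on the same subjects.
#'
#' @param lab,non_lab Numeric vectors of equal length (>= 2), both finite.
#' @return List with `mean_lab`, `mean_non_lab`, `mean_diff`, `t`, `df`, `p`,
#'   and `degenerate` (TRUE when all differences are identical so the t
#'   statistic is undefined; `t` and `p` are then `NA`).
#' @export
compare_lab_nonlab <- function(lab, non_lab) {
  stopifnot(length(lab) == length(non_lab), length(lab) >= 2,
            all(is.finite(lab)), all(is.finite(non_lab)))
  d <- lab - non_lab
  out <- list(mean_lab = mean(lab), mean_non_lab = mean(non_lab),
              mean_diff = mean(d))
  if (stats::sd(d) == 0) {
    out$t <- NA_real_
    out$df <- length(d) - 1
    out$p <- NA_real_
    out$degenerate <- TRUE
    return(out)
  }
  tt <- stats::t.test(lab, non_lab, paired = TRUE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out$degenerate <- FALSE
  out
}
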