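#' WHO HEARTS treatment-eligibility rules
#'
#' Antihypertensive treatment is indicated when any of, in fixed priority
#' order: (1) 10-year CVD risk in \[10%, 20%) with SBP >= 140 or DBP >= 90
#' mmHg; (2) risk >= 20% with SBP >= 130 or DBP >= 80 mmHg; (3) SBP >= 160 or
#' DBP >= 100 mmHg regardless of risk. Lipid-lowering treatment is indicated
#' when risk >= 20%, or at age >= 40 with diabetes. Risk enters as an exact
#' fraction; the "10%-19%" band is implemented as \[0.10, 0.20) so the two
#' risk bands partition \[0.10, Inf).
#'
#' @param risk_10y 10-year CVD risk as a fraction in \[0,1\].
#' @param sbp,dbp Mean blood pressures, mmHg.
#' @param age Years.
#' @param diabetes Logical.
#' @return Tibble with columns `elig_aht`, `elig_aht_rule`
#'   (`risk10_bp140`/`risk20_bp130`/`bp160_any`/`none`), `elig_llt`,
#'   `elig_llt_rule` (`risk20`/`diabetes_40plus`/`none`).
#' @examples
#' treatment_eligibility(0.15, sbp = 142, dbp = 70, age = 55, diabetes = FALSE)
#' @export
treatment_eligibility <- function(risk_10y, sbp, dbp, age, diabetes) {
  if (any(risk_10y < 0 | risk_10y > 1, na.rm = TRUE)) {
    stop("risk_10y must be a fraction in [0,1]")
  }
  r1 <- risk_10y >= 0.10 & risk_10y < 0.20 & (sbp >= 140 | dbp >= 90)
  r2 <- risk_10y >= 0.20 & (sbp >= 130 | dbp >= 80)
  r3 <- sbp >= 160 | dbp >= 100
  aht_rule <- ifelse(r1, "risk10_bp140",
              ifelse(r2, "risk20_bp130",
              ifelse(r3, "bp160_any", "none")))
  l1 <- risk_10y >= 0.20
  l2 <- age >= 40 & diabetes
  llt_rule <- ifelse(l1, "risk20",
              ifelse(l2, "diabetes_40plus", "none"))
  tibble::tibble(
    elig_aht = aht_rule != "none",
    elig_aht_rule = aht_rule,
    elig_llt = llt_rule != "none",
    elig_llt_rule = llt_rule
  )
}

#' Append eligibility columns to a scored data set
#'
#' @param scored Data frame with `risk_10y`, `sbp`, `dbp`, `age`, `diabetes`.
#' @return `scored` with the four eligibility columns appended.
#' @export
add_eligibility <- function(scored) {
  el <- treatment_eligibility(scored$risk_10y, scored$sbp, scored$dbp,
                              scored$age, scored$diabetes)
  dplyr::bind_cols(scored, el)
}
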