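#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## coefficient cache: loaded once per session from the shipped YAML
.coef_env <- new.env(parent = emptyenv())

.required_terms <- list(
  non_lab = c("ln_age", "ln_bmi", "ln_sbp_untreated", "ln_sbp_treated",
              "smoker", "diabetes"),
  lab = c("ln_age", "ln_total_chol", "ln_hdl", "ln_sbp_untreated",
          "ln_sbp_treated", "smoker", "diabetes")
)

#' Load and validate a Framingham coefficient file
#'
#' Reads the structured-text (YAML) file holding the sex-specific constants of
#' the Framingham general-CVD 10-year risk equations: per model variant and
#' sex, the regression weights on the log-transformed predictors, the 10-year
#' baseline survival \eqn{S_0(10)}, and the cohort mean linear predictor; plus
#' the ideal risk-factor reference profile used for heart-age inversion.
#'
#' @param path Path to a coefficient YAML file. Defaults to the file shipped
#'   with the package.
#' @return A validated nested list with elements `models` and
#'   `ideal_reference`.
#' @export
load_coefficient_file <- function(path = system.file("extdata",
                                                     "framingham_coefficients.yaml",
                                                     package = "heartage")) {
  stopifnot(nzchar(path), file.exists(path))
  cf <- yaml::read_yaml(path)
  for (variant in c("non_lab", "lab")) {
    for (sex in c("male", "female")) {
      m <- cf$models[[variant]][[sex]]
      if (is.null(m)) {
        stop("coefficient file missing model block: ", variant, "/", sex)
      }
      need <- .required_terms[[variant]]
      missing_terms <- setdiff(need, names(m$weights))
      if (length(missing_terms) > 0) {
        stop("coefficient file missing terms for ", variant, "/", sex, ": ",
             paste(missing_terms, collapse = ", "))
      }
      if (m$weights$ln_age <= 0) {
        stop("ln_age weight must be positive (risk monotone in age): ",
             variant, "/", sex)
      }
      s0 <- m$baseline_survival_10y
      if (!is.numeric(s0) || s0 <= 0 || s0 >= 1) {
        stop("baseline_survival_10y must lie in (0,1): ", variant, "/", sex)
      }
      if (!is.numeric(m$mean_linear_predictor)) {
        stop("mean_linear_predictor missing: ", variant, "/", sex)
      }
    }
  }
  ideal <- cf$ideal_reference
  stopifnot(
    identical(ideal$sbp, 125.0), identical(ideal$bmi, 22.5),
    isFALSE(ideal$treated), isFALSE(ideal$smoker), isFALSE(ideal$diabetes)
  )
  cf
}

.coefficients <- function() {
  if (is.null(.coef_env$cf)) {
    .coef_env$cf <- load_coefficient_file()
  }
  .coef_env$cf
}

#' Retrieve one coefficient set
#'
#' @param variant `"non_lab"` (office-based, BMI) or `"lab"` (lipid-based).
#' @param sex `"male"` or `"female"`.
#' @return A list with `weights` (named numeric), `baseline_survival_10y`,
#'   `mean_linear_predictor`, `variant`, `sex`, and `ideal` (the ideal
#'   reference profile).
#' @examples
#' fram_coefficients("non_lab", "female")$weights[["ln_age"]]
#' @export
fram_coefficients <- function(variant = c("non_lab", "lab"),
                              sex = c("male", "female")) {
  variant <- match.arg(variant)
  sex <- match.arg(sex)
  cf <- .coefficients()
  m <- cf$models[[variant]][[sex]]
  list(
    variant = variant,
    sex = sex,
    weights = unlist(m$weights),
    baseline_survival_10y = m$baseline_survival_10y,
    mean_linear_predictor = m$mean_linear_predictor,
    ideal = cf$ideal_reference
  )
}

#' The ideal risk-factor reference profile
#'
#' SBP 125 mmHg untreated, BMI 22.5 kg/m^2, non-smoker, non-diabetic; for the
#' lipid-based variant additionally total cholesterol 180 mg/dl and HDL
#' 45 mg/dl. This is the anchor against which predicted heart age is defined.
#'
#' @return Named list of ideal values.
#' @export
ideal_reference <- function() .coefficients()$ideal_reference
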