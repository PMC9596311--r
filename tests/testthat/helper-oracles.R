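# helpers shared across test files: random profile generation and
# independent oracles kept deliberately separate from the package's own
# computation paths

random_profiles <- function(n, sex, variant = "non_lab") {
  p <- data.frame(
    sex = sex,
    age = runif(n, 30, 74),
    sbp = runif(n, 90, 200),
    on_bp_treatment = runif(n) < 0.3,
    smoker = runif(n) < 0.3,
    diabetes = runif(n) < 0.15
  )
  if (variant == "non_lab") {
    p$bmi <- runif(n, 15, 50)
  } else {
    p$total_chol <- runif(n, 100, 320)
    p$hdl <- runif(n, 20, 100)
  }
  p
}

# brute-force term-by-term linear predictor, written directly against the
# shipped coefficient file rather than through fram_linear_predictor
oracle_lp <- function(profile, variant) {
  cf <- yaml::read_yaml(system.file("extdata", "framingham_coefficients.yaml",
                                    package = "heartage"))
  w <- cf$models[[variant]][[profile$sex]]$weights
  lp <- w$ln_age * log(profile$age)
  lp <- lp + if (profile$on_bp_treatment) {
    w$ln_sbp_treated * log(profile$sbp)
  } else {
    w$ln_sbp_untreated * log(profile$sbp)
  }
  if (variant == "non_lab") {
    lp <- lp + w$ln_bmi * log(profile$bmi)
  } else {
    lp <- lp + w$ln_total_chol * log(profile$total_chol) +
      w$ln_hdl * log(profile$hdl)
  }
  if (profile$smoker) lp <- lp + w$smoker
  if (profile$diabetes) lp <- lp + w$diabetes
  lp
}

ideal_profile_at_age <- function(age, sex, variant = "non_lab") {
  id <- ideal_reference()
  data.frame(sex = sex, age = age, sbp = id$sbp, on_bp_treatment = FALSE,
             bmi = id$bmi, total_chol = id$total_chol, hdl = id$hdl,
             smoker = FALSE, diabetes = FALSE)
}

# numeric root-finder oracle for heart age: the age at which the ideal
# profile reproduces the subject's 10-year risk; uses only the forward model
oracle_heart_age_bisect <- function(profile, variant = "non_lab",
                                    tol = 1e-9) {
  target <- fram_risk(profile, variant)$risk_10y
  f <- function(a) {
    fram_risk(ideal_profile_at_age(a, profile$sex, variant), variant,
              check_age = FALSE)$risk_10y - target
  }
  stats::uniroot(f, c(1, 1000), tol = tol)$root
}

# a small cleaned-and-scored multi-country data set reused by the survey and
# model tests
scored_fixture <- function(n_records = 800, seed = 7,
                           countries = c("Mongolia", "Ethiopia", "Nauru",
                                         "Bangladesh")) {
  ps <- steps_country_presets(n_records = n_records)[countries]
  sim <- simulate_multi_country(ps, seed)
  cl <- clean_records(sim$records)
  add_eligibility(score_heart_age(cl$clean))
}

# builds a synthetic regression data set with known log-odds effects and
# nested country-in-region intercepts; all covariates match the model spec
sim_glmm_data <- function(n_countries = 10, n_per = 300,
                          beta = c(smoker = 0, diabetes = 0,
                                   abdominal_obesity = 0),
                          sd_country = 0, sd_region = 0, intercept = -0.5,
                          n_regions = 5) {
  n <- n_countries * n_per
  country <- rep(sprintf("C%02d", seq_len(n_countries)), each = n_per)
  region <- rep(sprintf("R%d", 1 + (seq_len(n_countries) - 1) %% n_regions),
                each = n_per)
  u_c <- rnorm(n_countries, 0, sd_country)[as.integer(factor(country))]
  u_r <- rnorm(n_regions, 0, sd_region)[as.integer(factor(region))]
  d <- tibble::tibble(
    country = country, region = region,
    education4 = factor(sample(c("none", "primary", "secondary", "university"),
                               n, TRUE),
                        levels = c("none", "primary", "secondary", "university")),
    marital3 = factor(sample(c("never_married", "married_cohab", "div_sep_wid"),
                             n, TRUE),
                      levels = c("never_married", "married_cohab", "div_sep_wid")),
    work5 = factor(sample(c("unemployed", "employed_paid", "employed_unpaid",
                            "student", "homemaker"), n, TRUE),
                   levels = c("unemployed", "employed_paid", "employed_unpaid",
                              "student", "homemaker")),
    smoker = runif(n) < 0.25,
    diabetes = runif(n) < 0.15,
    abdominal_obesity = runif(n) < 0.3,
    high_cholesterol = runif(n) < 0.3
  )
  eta <- intercept + u_c + u_r +
    beta[["smoker"]] * d$smoker +
    beta[["diabetes"]] * d$diabetes +
    beta[["abdominal_obesity"]] * d$abdominal_obesity
  d$excess <- runif(n) < plogis(eta)
  d
}

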