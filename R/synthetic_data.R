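#' Parameters for one synthetic STEPS-like country survey
#'
#' Defines the marginal risk-factor distributions (means and dispersions), a
#' shared latent "metabolic" factor inducing positive cross-correlations
#' between adiposity, glycemia, lipids and blood pressure, binary-trait
#' prevalences, survey-design geometry (strata, PSUs, weight dispersion) and
#' error-injection rates for one country. Means and prevalences for the named
#' country presets are survey-reported values; dispersions are plausible
#' defaults chosen once (surveys report means with CIs, not SDs).
#'
#' When `fpg_meanlog` is `NULL` it is calibrated so that the fasting-glucose
#' criterion (FPG >= 126 mg/dl) accounts for 60% of the target total diabetes
#' prevalence and self-reported diagnosis tops up the remainder, making the
#' analytic total diabetes prevalence equal the target exactly.
#'
#' @param country,region,income,year Identification metadata; `region` one of
#'   the six WHO regions, `income` a World Bank band or `NA`.
#' @param n_records Number of survey rows to draw.
#' @param p_male Proportion male.
#' @param age_mean,age_sd Age distribution, truncated to 30--74 y.
#' @param sbp_mean,sbp_sd,bmi_mean,bmi_sd Marginal SBP (mmHg) and BMI
#'   (kg/m^2).
#' @param dbp_mean DBP location; DBP tracks SBP with slope 0.5.
#' @param waist_mean,waist_sd,waist_sex_gap Waist (cm): female mean, SD, and
#'   male-minus-female offset; waist is correlated 0.6 with BMI.
#' @param fpg_meanlog,fpg_sdlog FPG (mg/dl) is lognormal (right-skewed, as
#'   fasting glucose is); see calibration note above.
#' @param chol_mean,chol_sdlog Total cholesterol (mg/dl), lognormal with
#'   median `chol_mean`.
#' @param hdl_mean,hdl_sdlog HDL cholesterol (mg/dl), lognormal with median
#'   `hdl_mean`.
#' @param has_hdl Whether this survey measured HDL.
#' @param metabolic_loading Loading of the shared latent factor on BMI, FPG,
#'   total cholesterol and SBP (negated for HDL), in \[0,1).
#' @param psu_icc Share of continuous-trait variance at PSU level.
#' @param p_smoking,p_diabetes,p_bp_treatment,p_cvd_history Binary-trait
#'   prevalences (diabetes = target total: FPG criterion or self-report).
#' @param p_pregnant Pregnancy probability among women aged under 50.
#' @param edu_probs,marital_probs,work_probs Category probabilities over the
#'   7/6/9 raw survey codes.
#' @param n_strata,psus_per_stratum,weight_dispersion Design geometry;
#'   weights are lognormal with this log-SD (0 gives exactly equal weights).
#' @param bp_meas_sd,bp_first_bias Measurement noise SD of each BP reading
#'   and the additive bias of the discarded first reading.
#' @param implausible_rates Named per-variable probabilities of replacing a
#'   value with an out-of-plausible-range draw (see [inject_errors()]).
#' @param missing_rate Probability that a record has one analysis variable
#'   set missing.
#' @return Validated list of class `country_sim_params`.
#' @export
country_sim_params <- function(country = "Generic LMIC",
                               region = "Africa",
                               income = "lower_middle",
                               year = 2017,
                               n_records = 2000,
                               p_male = 0.5,
                               age_mean = 44, age_sd = 11,
                               sbp_mean = 128, sbp_sd = 18,
                               dbp_mean = 80,
                               bmi_mean = 25, bmi_sd = 4.8,
                               waist_mean = NULL, waist_sd = 11,
                               waist_sex_gap = 8,
                               fpg_meanlog = NULL, fpg_sdlog = 0.18,
                               chol_mean = 185, chol_sdlog = 0.19,
                               hdl_mean = 48, hdl_sdlog = 0.25,
                               has_hdl = TRUE,
                               metabolic_loading = 0.45,
                               psu_icc = 0.03,
                               p_smoking = 0.20,
                               p_diabetes = 0.10,
                               p_bp_treatment = 0.08,
                               p_cvd_history = 0.03,
                               p_pregnant = 0.02,
                               edu_probs = c(0.15, 0.15, 0.2, 0.2, 0.15, 0.1, 0.05),
                               marital_probs = c(0.12, 0.6, 0.05, 0.05, 0.1, 0.08),
                               work_probs = c(0.12, 0.2, 0.25, 0.04, 0.02, 0.17, 0.08, 0.08, 0.04),
                               n_strata = 5,
                               psus_per_stratum = 8,
                               weight_dispersion = 0.4,
                               bp_meas_sd = 4, bp_first_bias = 2.5,
                               implausible_rates = NULL,
                               missing_rate = 0.02) {
  if (is.null(waist_mean)) waist_mean <- 30 + 2.3 * bmi_mean
  if (is.null(fpg_meanlog)) {
    ## calibrate so P(FPG >= 126) = 0.6 * p_diabetes
    fpg_meanlog <- log(126) - stats::qnorm(1 - 0.6 * p_diabetes) * fpg_sdlog
  }
  if (is.null(implausible_rates)) {
    implausible_rates <- c(sbp = 0.004, dbp = 0.004, height = 0.003,
                           weight_kg = 0.003, bmi = 0.002, waist = 0.003,
                           fpg = 0.005, total_chol = 0.005)
  }
  p <- list(country = country, region = region, income = income, year = year,
            n_records = n_records, p_male = p_male,
            age_mean = age_mean, age_sd = age_sd,
            sbp_mean = sbp_mean, sbp_sd = sbp_sd, dbp_mean = dbp_mean,
            bmi_mean = bmi_mean, bmi_sd = bmi_sd,
            waist_mean = waist_mean, waist_sd = waist_sd,
            waist_sex_gap = waist_sex_gap,
            fpg_meanlog = fpg_meanlog, fpg_sdlog = fpg_sdlog,
            chol_mean = chol_mean, chol_sdlog = chol_sdlog,
            hdl_mean = hdl_mean, hdl_sdlog = hdl_sdlog, has_hdl = has_hdl,
            metabolic_loading = metabolic_loading, psu_icc = psu_icc,
            p_smoking = p_smoking, p_diabetes = p_diabetes,
            p_bp_treatment = p_bp_treatment, p_cvd_history = p_cvd_history,
            p_pregnant = p_pregnant,
            edu_probs = edu_probs, marital_probs = marital_probs,
            work_probs = work_probs,
            n_strata = n_strata, psus_per_stratum = psus_per_stratum,
            weight_dispersion = weight_dispersion,
            bp_meas_sd = bp_meas_sd, bp_first_bias = bp_first_bias,
            implausible_rates = implausible_rates,
            missing_rate = missing_rate)
  validate_sim_params(p)
  structure(p, class = "country_sim_params")
}

validate_sim_params <- function(p) {
  probs <- c(p_male = p$p_male, p_smoking = p$p_smoking,
             p_diabetes = p$p_diabetes, p_bp_treatment = p$p_bp_treatment,
             p_cvd_history = p$p_cvd_history, p_pregnant = p$p_pregnant,
             missing_rate = p$missing_rate, p$implausible_rates)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad) > 0) {
    stop("invalid simulation parameter (probability outside [0,1]): ",
         paste(bad, collapse = ", "))
  }
  scales <- c(age_sd = p$age_sd, sbp_sd = p$sbp_sd, bmi_sd = p$bmi_sd,
              waist_sd = p$waist_sd, fpg_sdlog = p$fpg_sdlog,
              chol_sdlog = p$chol_sdlog, hdl_sdlog = p$hdl_sdlog)
  bad <- names(scales)[scales <= 0]
  if (length(bad) > 0) {
    stop("invalid simulation parameter (scale must be positive): ",
         paste(bad, collapse = ", "))
  }
  if (p$metabolic_loading < 0 || p$metabolic_loading >= 1) {
    stop("invalid simulation parameter: metabolic_loading must be in [0,1)")
  }
  if (p$psu_icc < 0 || p$psu_icc >= 0.5) {
    stop("invalid simulation parameter: psu_icc must be in [0,0.5)")
  }
  for (nm in c("edu_probs", "marital_probs", "work_probs")) {
    if (abs(sum(p[[nm]]) - 1) > 1e-8) {
      stop("invalid simulation parameter: ", nm, " must sum to 1")
    }
  }
  if (p$n_records < 1 || p$n_strata < 1 || p$psus_per_stratum < 1) {
    stop("invalid simulation parameter: n_records/n_strata/psus_per_stratum")
  }
  invisible(p)
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate one STEPS-like country survey
#'
#' Draws raw survey records under the country's parameters: a latent
#' metabolic factor plus PSU-level effects generate correlated continuous
#' risk factors with the stated marginal means and SDs; three BP readings are
#' emitted as true pressure plus independent measurement noise (the first
#' with a small positive bias), so the protocol of discarding the first
#' reading is exercised; implausible values and missingness are then injected
#' at the stated rates. The truth ledger records the analytic prevalence of
#' every binary trait, the uncorrupted values behind every injected error,
#' and the weight construction.
#'
#' @param params A [country_sim_params()] object.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return List with `records` (tibble of raw survey rows) and `truth`
#'   (ledger list: `params`, `prevalence`, `corruptions`, `missing`,
#'   `weights`).
#' @export
simulate_country <- function(params, seed) {
  stopifnot(inherits(params, "country_sim_params"))
  validate_sim_params(params)
  p <- params
  withr::with_seed(seed, {
    n <- p$n_records
    sex <- ifelse(stats::runif(n) < p$p_male, "male", "female")
    age <- round(.rtrunc_norm(n, p$age_mean, p$age_sd, 29.5, 74.49))
    age <- pmin(pmax(age, 30), 74)

    ## design geometry: equal-sized strata, records spread over PSUs
    stratum <- rep(seq_len(p$n_strata), length.out = n)
    psu <- paste0(stratum, "-",
                  sample.int(p$psus_per_stratum, n, replace = TRUE))
    psu_key <- unique(psu)
    u_psu <- stats::setNames(stats::rnorm(length(psu_key)), psu_key)[psu]

    lam <- p$metabolic_loading
    icc <- p$psu_icc
    z <- stats::rnorm(n)
    draw_trait <- function(mean, sd, loading = lam) {
      ind <- loading * z + sqrt(1 - loading^2) * stats::rnorm(n)
      mean + sd * (sqrt(icc) * u_psu + sqrt(1 - icc) * ind)
    }
    sbp <- draw_trait(p$sbp_mean, p$sbp_sd)
    dbp <- p$dbp_mean + 0.5 * (sbp - p$sbp_mean) + stats::rnorm(n, 0, 7)
    bmi_resid <- lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
    bmi <- p$bmi_mean + p$bmi_sd * (sqrt(icc) * u_psu + sqrt(1 - icc) * bmi_resid)
    waist_center <- p$waist_mean + ifelse(sex == "male", p$waist_sex_gap, 0)
    waist <- waist_center + p$waist_sd *
      (0.6 * (bmi - p$bmi_mean) / p$bmi_sd +
         sqrt(1 - 0.36) * stats::rnorm(n))
    fpg <- exp(draw_trait(p$fpg_meanlog, p$fpg_sdlog))
    chol <- exp(draw_trait(log(p$chol_mean), p$chol_sdlog))
    hdl <- if (p$has_hdl) exp(draw_trait(log(p$hdl_mean), p$hdl_sdlog, -lam)) else NA_real_
    height <- ifelse(sex == "male",
                     stats::rnorm(n, 1.70, 0.07), stats::rnorm(n, 1.58, 0.065))
    weight_kg <- pmax(bmi, 10.5) * height^2

    ## diabetes: FPG criterion carries 60% of the target (by calibration of
    ## fpg_mean); self-report tops up the rest, plus half of the high-FPG
    ## group also reports a diagnosis
    p_fpg <- 1 - stats::pnorm(log(126), p$fpg_meanlog, p$fpg_sdlog)
    p_self_extra <- max(0, (p$p_diabetes - p_fpg) / (1 - p_fpg))
    high_fpg <- fpg >= 126
    self_dm <- ifelse(high_fpg, stats::runif(n) < 0.5,
                      stats::runif(n) < p_self_extra)
    p_diab_true <- p_fpg + (1 - p_fpg) * p_self_extra

    smoker <- stats::runif(n) < p$p_smoking
    on_bp_treatment <- stats::runif(n) < p$p_bp_treatment
    cvd_history <- stats::runif(n) < p$p_cvd_history
    preg_eligible <- sex == "female" & age < 50
    pregnant <- preg_eligible & stats::runif(n) < p$p_pregnant

    education_raw <- sample.int(7, n, replace = TRUE, prob = p$edu_probs)
    marital_raw <- sample.int(6, n, replace = TRUE, prob = p$marital_probs)
    work_raw <- sample.int(9, n, replace = TRUE, prob = p$work_probs)

    sample_weight <- stats::rlnorm(n, 0, p$weight_dispersion)

    mk_bp <- function(true, bias) true + bias + stats::rnorm(n, 0, p$bp_meas_sd)
    records <- tibble::tibble(
      pid = paste0(p$country, "-", seq_len(n)),
      country = p$country, region = p$region, income = p$income,
      year = p$year,
      stratum = stratum, psu = psu, sample_weight = sample_weight,
      sex = sex, age = age,
      sbp1 = mk_bp(sbp, p$bp_first_bias), sbp2 = mk_bp(sbp, 0),
      sbp3 = mk_bp(sbp, 0),
      dbp1 = dbp + p$bp_first_bias / 2 + stats::rnorm(n, 0, p$bp_meas_sd / 1.5),
      dbp2 = dbp + stats::rnorm(n, 0, p$bp_meas_sd / 1.5),
      dbp3 = dbp + stats::rnorm(n, 0, p$bp_meas_sd / 1.5),
      height = height, weight_kg = weight_kg, waist = waist,
      fpg = fpg, total_chol = chol, hdl = hdl,
      self_reported_diabetes = self_dm, on_bp_treatment = on_bp_treatment,
      smoker = smoker, pregnant = pregnant, cvd_history = cvd_history,
      education_raw = education_raw, marital_raw = marital_raw,
      work_raw = work_raw
    )

    ## analytic prevalences (exact under the generating model)
    p_female_u50 <- mean(sex == "female" & age < 50)  # realized share
    prevalence <- tibble::tibble(
      trait = c("smoker", "diabetes", "on_bp_treatment", "cvd_history",
                "high_cholesterol", "pregnant_among_women_u50"),
      p_true = c(p$p_smoking, p_diab_true, p$p_bp_treatment,
                 p$p_cvd_history,
                 1 - stats::pnorm(log(200), log(p$chol_mean), p$chol_sdlog),
                 p$p_pregnant)
    )

    inj <- inject_errors(records, rates = p$implausible_rates,
                         missing_rate = p$missing_rate,
                         seed = seed + 1L)
    list(records = inj$records,
         truth = list(params = p, prevalence = prevalence,
                      corruptions = inj$corruptions, missing = inj$missing,
                      weights = list(distribution = "lognormal",
                                     sdlog = p$weight_dispersion)))
  })
}

## out-of-plausible-range bands used for injected errors; BP corruption
## replaces readings 2 and 3 with the same drawn value so the analysis mean
## is guaranteed out of range, and BMI corruption uses in-range height/weight
## pairs whose ratio is out of range
.corruption_bands <- list(
  sbp = rbind(c(40, 69), c(271, 330)),
  dbp = rbind(c(10, 29), c(151, 220)),
  height = rbind(c(0.30, 0.95), c(2.55, 4.00)),
  weight_kg = rbind(c(1, 11.5), c(305, 600)),
  waist = rbind(c(5, 29), c(205, 400)),
  fpg = rbind(c(5, 44), c(545, 900)),
  total_chol = rbind(c(10, 66), c(780, 1500)),
  bmi = rbind(c(3.1, 9.5), c(81, 120))
)

.draw_out_of_band <- function(n, bands) {
  side <- sample.int(nrow(bands), n, replace = TRUE)
  stats::runif(n, bands[side, 1], bands[side, 2])
}

#' Inject implausible values and missingness into raw records
#'
#' Each record is corrupted in at most one variable: a record is selected
#' with probability `sum(rates)` and the variable chosen proportionally to
#' the rates, so the per-variable corruption probability equals its stated
#' rate exactly. Corrupted values are drawn uniformly from documented
#' out-of-plausible-range bands. BP corruption overwrites readings 2 and 3
#' with the same value; BMI corruption overwrites height and weight with an
#' in-range pair whose implied BMI is out of range. Missingness independently
#' blanks one analysis variable per selected record. Every change is listed
#' in the returned ledgers.
#'
#' @param records Raw records tibble.
#' @param rates Named per-variable corruption probabilities (any of `sbp`,
#'   `dbp`, `height`, `weight_kg`, `waist`, `fpg`, `total_chol`, `bmi`).
#' @param missing_rate Per-record probability of one missing analysis value.
#' @param seed Integer seed.
#' @return List: `records` (corrupted), `corruptions` (tibble pid, variable,
#'   original, corrupted), `missing` (tibble pid, variable).
#' @export
inject_errors <- function(records, rates, missing_rate = 0, seed) {
  stopifnot(all(rates >= 0), all(rates <= 1), sum(rates) <= 1)
  unknown <- setdiff(names(rates), names(.corruption_bands))
  if (length(unknown) > 0) {
    stop("inject_errors: no corruption band for: ",
         paste(unknown, collapse = ", "))
  }
  withr::with_seed(seed, {
    n <- nrow(records)
    corr_rows <- integer(0)
    corr_var <- character(0)
    if (length(rates) > 0 && sum(rates) > 0) {
      hit <- stats::runif(n) < sum(rates)
      corr_rows <- which(hit)
      corr_var <- sample(names(rates), length(corr_rows), replace = TRUE,
                         prob = rates / sum(rates))
    }
    ledger <- list()
    for (v in unique(corr_var)) {
      rows <- corr_rows[corr_var == v]
      m <- length(rows)
      if (v == "sbp" || v == "dbp") {
        val <- .draw_out_of_band(m, .corruption_bands[[v]])
        c2 <- paste0(v, "2"); c3 <- paste0(v, "3")
        ledger[[v]] <- tibble::tibble(pid = records$pid[rows], variable = v,
                                      original = (records[[c2]][rows] +
                                                    records[[c3]][rows]) / 2,
                                      corrupted = val)
        records[[c2]][rows] <- val
        records[[c3]][rows] <- val
      } else if (v == "bmi") {
        side <- sample.int(2, m, replace = TRUE)
        bmi_t <- stats::runif(m, .corruption_bands$bmi[side, 1],
                              .corruption_bands$bmi[side, 2])
        h <- ifelse(side == 1, 2.0, 1.0)  # keeps height/weight in range
        ledger[[v]] <- tibble::tibble(
          pid = records$pid[rows], variable = v,
          original = records$weight_kg[rows] / records$height[rows]^2,
          corrupted = bmi_t)
        records$height[rows] <- h
        records$weight_kg[rows] <- bmi_t * h^2
      } else {
        val <- .draw_out_of_band(m, .corruption_bands[[v]])
        ledger[[v]] <- tibble::tibble(pid = records$pid[rows], variable = v,
                                      original = records[[v]][rows],
                                      corrupted = val)
        records[[v]][rows] <- val
      }
    }
    corruptions <- if (length(ledger) > 0) dplyr::bind_rows(ledger) else
      tibble::tibble(pid = character(0), variable = character(0),
                     original = numeric(0), corrupted = numeric(0))

    missing <- tibble::tibble(pid = character(0), variable = character(0))
    if (missing_rate > 0) {
      miss_vars <- c("smoker", "waist", "fpg", "total_chol", "height")
      hit <- which(stats::runif(n) < missing_rate)
      if (length(hit) > 0) {
        mv <- sample(miss_vars, length(hit), replace = TRUE)
        for (v in unique(mv)) {
          rows <- hit[mv == v]
          records[[v]][rows] <- NA
        }
        missing <- tibble::tibble(pid = records$pid[hit], variable = mv)
      }
    }
    list(records = records, corruptions = corruptions, missing = missing)
  })
}

#' Derive a per-country substream seed from a master seed
#'
#' Deterministic hash of the master seed and the country name so that each
#' country's records are identical whether it is simulated alone or as part
#' of any multi-country batch. The result stays below 2^31.
#'
#' @param seed Master integer seed.
#' @param country Country name.
#' @return Integer substream seed.
#' @export
country_substream_seed <- function(seed, country) {
  h <- sum(utf8ToInt(country) * seq_along(utf8ToInt(country)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Simulate a pooled multi-country STEPS-like data set
#'
#' Each country is generated from an independent substream derived from the
#' master seed ([country_substream_seed()]), so adding or removing a country
#' never perturbs another country's records.
#'
#' @param params_list List of [country_sim_params()] objects with distinct
#'   country codes.
#' @param seed Master integer seed.
#' @return List with pooled `records` and per-country `truth` ledgers.
#' @export
simulate_multi_country <- function(params_list, seed) {
  stopifnot(length(params_list) >= 1)
  countries <- vapply(params_list, function(p) p$country, character(1))
  if (anyDuplicated(countries)) {
    stop("duplicate country codes: ",
         paste(unique(countries[duplicated(countries)]), collapse = ", "))
  }
  sims <- lapply(params_list, function(p) {
    simulate_country(p, country_substream_seed(seed, p$country))
  })
  list(
    records = dplyr::bind_rows(lapply(sims, `[[`, "records")),
    truth = stats::setNames(lapply(sims, `[[`, "truth"), countries)
  )
}

#' Country presets with survey-reported risk-factor levels
#'
#' Sixteen named country presets whose mean age, proportion male, mean SBP,
#' mean BMI, smoking prevalence and total diabetes prevalence are set to the
#' weighted values reported for the corresponding national STEPS surveys,
#' spanning all six WHO regions; dispersions and design geometry are the
#' package defaults (not survey values). One country (Tokelau) carries no
#' income classification, mirroring its exclusion from income groupings.
#'
#' @param n_records Rows per country (recycled).
#' @return Named list of [country_sim_params()] objects.
#' @export
steps_country_presets <- function(n_records = 2000) {
  spec <- list(
    list("Ethiopia", "Africa", "low", 2015, 43, .556, 123.3, 20.7, .057, .032),
    list("Zambia", "Africa", "lower_middle", 2017, 43, .489, 126.3, 23.8, .145, .108),
    list("Ecuador", "Americas", "upper_middle", 2018, 47, .480, 122.1, 28.0, .128, .139),
    list("Guyana", "Americas", "upper_middle", 2016, 46, .454, 129.4, 28.1, .122, .232),
    list("Jordan", "Eastern Mediterranean", "upper_middle", 2019, 45, .412, 120.5, 30.2, .358, .173),
    list("Sudan", "Eastern Mediterranean", "low", 2016, 44, .532, 131.3, 24.2, .090, .109),
    list("Belarus", "Europe", "upper_middle", 2017, 48, .466, 137.1, 27.8, .299, .075),
    list("Republic of Moldova", "Europe", "lower_middle", 2013, 46, .522, 136.9, 27.6, .261, .102),
    list("Bangladesh", "Southeast Asia", "lower_middle", 2018, 46, .517, 123.1, 22.7, .283, .125),
    list("Nepal", "Southeast Asia", "low", 2019, 45, .472, 127.5, 23.4, .208, .085),
    list("Mongolia", "Western Pacific", "lower_middle", 2019, 44, .499, 124.3, 27.0, .285, .124),
    list("Nauru", "Western Pacific", "upper_middle", 2016, 43, .518, 126.6, 35.6, .420, .301),
    list("Tokelau", "Western Pacific", NA_character_, 2014, 45, .462, 130.5, 34.6, .565, .556),
    list("Tuvalu", "Western Pacific", "upper_middle", 2015, 47, .516, 139.7, 33.8, .351, .188),
    list("Vietnam", "Western Pacific", "lower_middle", 2015, 46, .496, 123.1, 22.4, .297, .043),
    list("Generic LMIC", "Africa", "lower_middle", 2017, 44, .50, 128.0, 25.0, .200, .100)
  )
  out <- lapply(spec, function(s) {
    country_sim_params(country = s[[1]], region = s[[2]], income = s[[3]],
                       year = s[[4]], n_records = n_records,
                       age_mean = s[[5]], p_male = s[[6]],
                       sbp_mean = s[[7]], bmi_mean = s[[8]],
                       p_smoking = s[[9]], p_diabetes = s[[10]])
  })
  stats::setNames(out, vapply(spec, function(s) s[[1]], character(1)))
}
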