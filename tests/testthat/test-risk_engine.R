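test_that("calculator inputs are clamped to the accepted ranges", {
  p <- data.frame(sbp = c(205, 125, 80), bmi = c(30, 22.5, 12.8))
  out <- clamp_calculator_inputs(p)
  expect_equal(out$sbp, c(200, 125, 90))
  expect_equal(out$bmi, c(30, 22.5, 15))
  expect_equal(out$clamped, c(TRUE, FALSE, TRUE))

  expect_error(clamp_calculator_inputs(data.frame(bmi = 25)), "sbp")
  expect_error(clamp_calculator_inputs(data.frame(sbp = 120)), "bmi")
  expect_silent(clamp_calculator_inputs(data.frame(sbp = 120), "lab"))
})

test_that("linear predictor equals brute-force term summation", {
  # degenerate unit-input check: all log terms vanish, indicators off
  unit <- data.frame(sex = "male", age = 1, sbp = 1, on_bp_treatment = FALSE,
                     bmi = 1, smoker = FALSE, diabetes = FALSE)
  expect_equal(fram_linear_predictor(unit, check_age = FALSE), 0)

  set.seed(11)
  for (variant in c("non_lab", "lab")) {
    for (sex in c("male", "female")) {
      profs <- random_profiles(1000, sex, variant)
      lp <- fram_linear_predictor(profs, variant)
      lp_oracle <- vapply(seq_len(nrow(profs)), function(i) {
        oracle_lp(profs[i, ], variant)
      }, numeric(1))
      expect_equal(lp, lp_oracle, tolerance = 1e-10)
    }
  }
})

test_that("treatment toggle shifts the linear predictor by the weight gap", {
  p <- data.frame(sex = "female", age = 61, sbp = 140, on_bp_treatment = TRUE,
                  bmi = 28, smoker = TRUE, diabetes = FALSE)
  p_off <- transform(p, on_bp_treatment = FALSE)
  w <- fram_coefficients("non_lab", "female")$weights
  expect_equal(
    fram_linear_predictor(p) - fram_linear_predictor(p_off),
    (w[["ln_sbp_treated"]] - w[["ln_sbp_untreated"]]) * log(140),
    tolerance = 1e-12
  )
})

test_that("risk is a proper probability, monotone in its risk factors", {
  # LP = mean LP gives risk 1 - S0 by construction
  for (sex in c("male", "female")) {
    cs <- fram_coefficients("non_lab", sex)
    grid <- expand.grid(age = c(30, 45, 60, 74), sbp = c(90, 140, 200),
                        bmi = c(15, 30, 50), on_bp_treatment = c(FALSE, TRUE),
                        smoker = c(FALSE, TRUE), diabetes = c(FALSE, TRUE))
    grid$sex <- sex
    r <- fram_risk(grid)$risk_10y
    expect_true(all(r > 0 & r < 1))
    # increasing age, sbp, bmi with all else fixed never lowers risk
    for (v in c("age", "sbp", "bmi")) {
      others <- setdiff(names(grid), c(v, "sex"))
      ord <- do.call(order, c(grid[others], grid[v]))
      g <- grid[ord, ]
      rr <- fram_risk(g)$risk_10y
      same_block <- !Reduce(`|`, lapply(g[others], function(x) {
        x[-1] != x[-length(x)]
      }))
      expect_true(all(diff(rr)[same_block] > 0))
    }
    # worsening an indicator never decreases risk
    base <- data.frame(sex = sex, age = 50, sbp = 130,
                       on_bp_treatment = FALSE, bmi = 27,
                       smoker = FALSE, diabetes = FALSE)
    expect_gt(fram_risk(transform(base, smoker = TRUE))$risk_10y,
              fram_risk(base)$risk_10y)
    expect_gt(fram_risk(transform(base, diabetes = TRUE))$risk_10y,
              fram_risk(base)$risk_10y)
  }
})

test_that("ideal male profile risk rises from age 30 to 74", {
  r30 <- fram_risk(ideal_profile_at_age(30, "male"))$risk_10y
  r74 <- fram_risk(ideal_profile_at_age(74, "male"))$risk_10y
  expect_lt(r30, r74)
  expect_equal(r30, 0.01776113, tolerance = 1e-6)  # frozen from oracle
})

test_that("lab and non-lab risks are both proper for the same person", {
  p <- data.frame(sex = "female", age = 55, sbp = 135, on_bp_treatment = FALSE,
                  bmi = 29, total_chol = 210, hdl = 45, smoker = FALSE,
                  diabetes = FALSE)
  r_lab <- fram_risk(p, "lab")$risk_10y
  r_nonlab <- fram_risk(p, "non_lab")$risk_10y
  expect_true(r_lab > 0 && r_lab < 1)
  expect_true(r_nonlab > 0 && r_nonlab < 1)
  expect_true(is.finite(r_lab - r_nonlab))
})

test_that("paired comparison matches the hand-computed t formula", {
  non_lab <- c(1, 2, 3, 4, 5)
  lab <- c(2, 2, 5, 4, 7)
  res <- compare_lab_nonlab(lab, non_lab)
  d <- lab - non_lab
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), length(d) - 1)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
  expect_equal(res$mean_diff, 1)

  same <- compare_lab_nonlab(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_true(same$degenerate)
  expect_true(is.na(same$p))
})

test_that("paired t-test holds its nominal type-I error under the null", {
  set.seed(202)
  n_rep <- 1000
  rejections <- vapply(seq_len(n_rep), function(i) {
    a <- rnorm(1000)
    b <- a + rnorm(1000)  # paired, true mean shift zero
    compare_lab_nonlab(b, a)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se3 <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), se3)
})
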