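test_that("weighted proportion matches hand computation", {
  res <- weighted_prevalence(c(1, 0, 1, 0), w = c(2, 1, 1, 4))
  expect_equal(res$proportion, 3 / 8)

  # equal weights reduce to the unweighted proportion
  res2 <- weighted_prevalence(c(rep(1, 3), rep(0, 7)), w = rep(2.5, 10))
  expect_equal(res2$proportion, 0.30)

  expect_error(weighted_prevalence(numeric(0), numeric(0)), "empty")
  expect_error(weighted_prevalence(c(1, 0), c(0, 0)), "zero")
})

test_that("linearized SE matches the SRS closed form on equal weights", {
  set.seed(41)
  n <- 2000
  y <- runif(n) < 0.3
  res <- weighted_prevalence(y, rep(1, n))
  p <- mean(y)
  se_srs <- sqrt(p * (1 - p) / n)
  expect_lt(abs(res$se - se_srs) / se_srs, 0.01)
  expect_true(res$ci_lo <= res$proportion && res$proportion <= res$ci_hi)
})

test_that("between-PSU variance matches a brute-force two-PSU computation", {
  y <- c(1, 0, 0, 0, 1, 1, 1, 0)
  w <- c(1, 2, 1, 1, 2, 1, 1, 1)
  psu <- rep(c("a", "b"), each = 4)
  res <- weighted_prevalence(y, w, psu = psu, stratum = rep(1, 8))
  # brute force: z_i = w_i (y_i - p) / W, PSU totals, n/(n-1) * centered SSQ
  p <- sum(w * y) / sum(w)
  z <- w * (y - p) / sum(w)
  tot <- tapply(z, psu, sum)
  v <- 2 / 1 * sum((tot - mean(tot))^2)
  expect_equal(res$se, sqrt(v), tolerance = 1e-12)
})

test_that("proportions are invariant to rescaling all weights", {
  set.seed(42)
  y <- runif(50) < 0.4
  w <- runif(50, 0.5, 3)
  psu <- sample(1:5, 50, replace = TRUE)
  a <- weighted_prevalence(y, w, psu, rep(1, 50))
  b <- weighted_prevalence(y, w * 17, psu, rep(1, 50))
  expect_equal(a$proportion, b$proportion)
  expect_equal(a$se, b$se)
})

test_that("category prevalences sum to one in every domain", {
  scored <- scored_fixture(400, seed = 13)
  tab <- category_prevalence_table(scored)
  sums <- tab |>
    dplyr::group_by(country, sex) |>
    dplyr::summarise(s = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # degenerate composition: all equal-PHA records give (0,1,0,0)
  one <- scored[rep(1, 10), ]
  one$gap_class <- factor("equal", levels = levels(scored$gap_class))
  tab1 <- category_prevalence_table(one)
  expect_equal(tab1$proportion[tab1$category == "equal"], 1)
  expect_equal(sum(tab1$proportion[tab1$category != "equal"]), 0)
})

test_that("eligibility among excess handles denominators and flags empties", {
  scored <- scored_fixture(400, seed = 14)
  tab <- eligibility_among_excess(scored, thresholds = c(1, 20))
  expect_true(all(tab$proportion[!tab$empty_domain] >= 0 &
                    tab$proportion[!tab$empty_domain] <= 1))
  # all-eligible degenerate domain
  d <- scored[scored$excess, ][1:5, ]
  d$elig_aht <- TRUE
  t2 <- eligibility_among_excess(d, thresholds = 1)
  expect_true(all(t2$proportion[t2$therapy == "elig_aht"] == 1))
  # empty denominator is flagged, not dropped
  d2 <- scored[1:5, ]
  d2$pha_coded <- as.character(d2$age - 3)
  d2$gap_class <- classify_gap(d2$age, d2$pha_coded)
  t3 <- eligibility_among_excess(d2, thresholds = 1)
  expect_true(all(t3$empty_domain))
  expect_equal(nrow(t3), nrow(dplyr::distinct(d2, country, sex)) * 2)
})

test_that("weighted quintiles use order statistics and a lower-tie rule", {
  x <- 1:100
  q <- weighted_quantile(x, rep(1, 100), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(q, c(20, 40, 60, 80))

  scored <- scored_fixture(300, seed = 15, countries = "Mongolia")
  tab <- risk_quintile_strata(scored)
  expect_true(all(sort(unique(tab$quintile)) %in% 1:5))
  # all risks identical collapse into Q1
  s2 <- scored[1:20, ]
  s2$risk_10y <- 0.1
  t2 <- risk_quintile_strata(s2)
  expect_true(all(t2$quintile == 1))
})

test_that("very-high prevalence rises across risk quintiles by construction", {
  scored <- scored_fixture(1500, seed = 16, countries = "Nauru")
  tab <- risk_quintile_strata(scored)
  vh <- tab[tab$category == "very_high", ]
  vh <- vh[order(vh$quintile), ]
  # risk drives heart age, so the trend must be monotone up to MC noise
  expect_true(all(diff(vh$proportion) > -0.05))
  expect_gt(vh$proportion[nrow(vh)], vh$proportion[1])
})

test_that("one-way ANOVA matches the textbook computation", {
  res <- group_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 4)

  # identical group means and spreads: no between-group variance
  res0 <- group_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_lt(res0$F, 1e-20)

  expect_warning(
    group_anova(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
    "excluding"
  )
  expect_error(suppressWarnings(group_anova(c(1, 2, 3), c("a", "a", "b"))),
               "usable groups")
})

test_that("ANOVA p values are uniform under a null simulation", {
  set.seed(43)
  pvals <- replicate(400, {
    group_anova(rnorm(18), rep(c("a", "b", "c"), each = 6))$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.001)
})

test_that("sankey flow table counts every record once", {
  scored <- scored_fixture(300, seed = 17, countries = "Vietnam")
  tab <- sankey_flow_table(scored)
  expect_equal(sum(tab$count), nrow(scored))
  expect_true(all(c("sex", "age_band", "pha_band", "count") %in% names(tab)))
})
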