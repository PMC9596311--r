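#!/usr/bin/env Rscript
# Stage 5: correlates of excess heart age and of treatment eligibility.
# Mixed-effects logistic models with random intercepts for country nested in
# region; odds ratios with Wald 95% CIs. Survey weights are deliberately not
# used in these models.

suppressMessages(library(heartage))

scored <- read.csv("results/scored_records.csv")
scored$gap_class <- factor(scored$gap_class,
                           levels = c("low", "equal", "high", "very_high"))
# re-harmonize categorical covariates so reference levels are fixed
scored$education4 <- harmonize_education(scored$education_raw)
scored$marital3 <- harmonize_marital(scored$marital_raw)
scored$work5 <- harmonize_work(scored$work_raw)

for (outcome in c("excess_pha", "elig_aht", "elig_llt")) {
  fit <- fit_glmm(scored, outcome, nAGQ = 0)
  tab <- or_table(fit)
  write.csv(tab, sprintf("results/or_table_%s.csv", outcome),
            row.names = FALSE)
  message(sprintf("%s (n=%d, %s): smoker OR %.2f, abdominal obesity OR %.2f",
                  outcome, fit$n, fit$status,
                  ifelse(any(fit$table$term == "smokerTRUE"),
                         fit$table$or[fit$table$term == "smokerTRUE"], NA),
                  fit$table$or[fit$table$term == "abdominal_obesityTRUE"]))
  vc <- fit$varcomp
  message(sprintf("  variance: country-in-region %.3f, region %.3f",
                  vc$variance[vc$group == "country_in_region"],
                  vc$variance[vc$group == "region"]))
}
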