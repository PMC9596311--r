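#!/usr/bin/env Rscript
# Stage 4: design-aware summaries. Survey-weighted prevalence of the four
# heart-age gap categories by country and sex, eligibility among people with
# excess heart age (at gap thresholds 1/5/10/20 years), category prevalence
# within country-level risk quintiles, the chronological-vs-heart-age flow
# table, and one-way ANOVAs of very-high prevalence across regions/income.

suppressMessages({
  library(heartage)
  library(dplyr)
})

scored <- read.csv("results/scored_records.csv")
scored$gap_class <- factor(scored$gap_class,
                           levels = c("low", "equal", "high", "very_high"))

cat_tab <- category_prevalence_table(scored)
write.csv(cat_tab, "results/category_prevalence.csv", row.names = FALSE)

elig_tab <- eligibility_among_excess(scored)
write.csv(elig_tab, "results/eligibility_among_excess.csv", row.names = FALSE)

quint <- risk_quintile_strata(scored)
write.csv(quint, "results/risk_quintile_prevalence.csv", row.names = FALSE)

sankey <- sankey_flow_table(scored)
write.csv(sankey, "results/sankey_flow.csv", row.names = FALSE)

vh <- cat_tab |>
  filter(category == "very_high") |>
  group_by(country) |>
  summarise(prevalence = mean(proportion), .groups = "drop") |>
  left_join(distinct(scored, country, region, income), by = "country")
write.csv(vh, "results/very_high_by_country.csv", row.names = FALSE)

a_region <- group_anova(vh$prevalence, vh$region)
ok_inc <- !is.na(vh$income)
a_income <- group_anova(vh$prevalence[ok_inc], vh$income[ok_inc])
write.csv(data.frame(
  grouping = c("region", "income"),
  F = c(a_region$F, a_income$F),
  p = c(a_region$p, a_income$p)
), "results/anova_very_high.csv", row.names = FALSE)

message(sprintf("very-high heart-age prevalence by country: %.1f%% - %.1f%%",
                100 * min(vh$prevalence), 100 * max(vh$prevalence)))
message(sprintf("ANOVA across regions: F = %.2f (p = %.3f); income: F = %.2f (p = %.3f)",
                a_region$F, a_region$p, a_income$F, a_income$p))
exc <- elig_tab |> filter(threshold == 1, !empty_domain)
message(sprintf("median country-sex eligibility among excess: aht %.1f%%, llt %.1f%%",
                100 * median(exc$proportion[exc$therapy == "elig_aht"]),
                100 * median(exc$proportion[exc$therapy == "elig_llt"])))
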