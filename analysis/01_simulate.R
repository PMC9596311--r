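#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-country STEPS-like study population.
# Sixteen country presets spanning all six WHO regions, with survey-reported
# risk-factor means/prevalences and known ground truth, including injected
# implausible values and missingness.

suppressMessages(library(heartage))

seed <- 20260921L
n_per_country <- 2000
dir.create("results", showWarnings = FALSE)

presets <- steps_country_presets(n_records = n_per_country)
sim <- simulate_multi_country(presets, seed)

write.csv(sim$records, "results/raw_records.csv", row.names = FALSE)
truth_prev <- do.call(rbind, lapply(names(sim$truth), function(cty) {
  cbind(country = cty, sim$truth[[cty]]$prevalence)
}))
write.csv(truth_prev, "results/truth_prevalence.csv", row.names = FALSE)
corr <- do.call(rbind, lapply(sim$truth, function(t) t$corruptions))
write.csv(corr, "results/truth_corruptions.csv", row.names = FALSE)

message(sprintf("simulated %d records across %d countries (seed %d)",
                nrow(sim$records), length(presets), seed))
message(sprintf("injected %d implausible values and logged them", nrow(corr)))
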