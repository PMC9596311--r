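#!/usr/bin/env Rscript
# Stage 3: risk scoring and heart-age inversion. Computes the non-laboratory
# Framingham 10-year CVD risk (with calculator clamping), inverts it to the
# predicted heart age against the ideal reference profile, applies the
# "<30"/">80" censoring, classifies the gap versus chronological age, and
# appends the WHO HEARTS treatment-eligibility flags.

suppressMessages(library(heartage))

clean <- read.csv("results/clean_records.csv")
scored <- add_eligibility(score_heart_age(clean, variant = "non_lab"))
write.csv(scored, "results/scored_records.csv", row.names = FALSE)

message(sprintf("scored %d records; %.1f%% clamped into calculator range",
                nrow(scored), 100 * mean(scored$clamped)))
message(sprintf("gap classes: %s",
                paste(names(table(scored$gap_class)), table(scored$gap_class),
                      sep = "=", collapse = ", ")))
message(sprintf("censored: %d '<30', %d '>80'",
                sum(scored$pha_coded == "<30"), sum(scored$pha_coded == ">80")))
message(sprintf("eligible among all: antihypertensive %.1f%%, lipid %.1f%%",
                100 * mean(scored$elig_aht), 100 * mean(scored$elig_llt)))
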