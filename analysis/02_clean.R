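#!/usr/bin/env Rscript
# Stage 2: population selection and plausibility cleaning. Applies the
# age-30-74 / non-pregnant / no-CVD-history inclusion rules, the plausibility
# ranges, and complete-case filtering; writes the cleaned data, the
# per-record drop ledger and the per-country flow table.

suppressMessages(library(heartage))

raw <- read.csv("results/raw_records.csv")
res <- clean_records(raw)

write.csv(res$clean, "results/clean_records.csv", row.names = FALSE)
write.csv(res$drops, "results/drop_ledger.csv", row.names = FALSE)
flow <- cleaning_report(res$decisions)
write.csv(flow, "results/cleaning_flow.csv", row.names = FALSE)

message(sprintf("kept %d of %d records (%.1f%%)", nrow(res$clean), nrow(raw),
                100 * nrow(res$clean) / nrow(raw)))
tab <- sort(table(res$drops$reason), decreasing = TRUE)
message("top drop reasons: ",
        paste(names(tab), tab, sep = "=", collapse = ", "))

# cross-check: every injected corruption must appear in the drop ledger
corr <- read.csv("results/truth_corruptions.csv")
dropped <- corr$pid %in% res$drops$pid
message(sprintf("injected corruptions recovered by cleaning: %d/%d",
                sum(dropped), nrow(corr)))
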