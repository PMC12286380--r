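#!/usr/bin/env Rscript
# Stage 2: build call transitions within each F2F session, classify them
# as exchange (caller changes) or repeated (same caller), count the
# overlapping interactions and summarize how concentrated the inter-call
# intervals are.

library(callexchange)
library(readr)

events <- read_call_table("scratch/simulated_calls.csv")
f2f_calls <- filter_events(events, vocal_type = "call", phase = "F2F")
trans <- transitions_by_phase(f2f_calls)
parts <- split_by_kind(trans)

summary_tbl <- tibble::tibble(
  n_transitions = nrow(trans),
  n_exchange = nrow(parts$exchange),
  n_repeated = nrow(parts$repeated),
  n_overlap_exchange = count_overlaps(parts$exchange),
  fraction_within_10s = fraction_within(trans$interval, 10)
)
write_csv(summary_tbl, "results/transitions_summary.csv")
write_transition_table(trans, "scratch/transitions_f2f.csv")

solo_trans <- transitions_by_phase(
  filter_events(events, vocal_type = "call", phase = c("PRE", "POST")))
write_transition_table(solo_trans, "scratch/transitions_solo.csv")

cat(sprintf("F2F transitions: %d (%d exchange, %d repeated)\n",
            nrow(trans), nrow(parts$exchange), nrow(parts$repeated)))
cat(sprintf("overlapping exchange interactions: %d (%.2f%%)\n",
            count_overlaps(parts$exchange),
            100 * count_overlaps(parts$exchange) / nrow(parts$exchange)))
cat(sprintf("fraction of F2F intervals within 10 s: %.3f\n",
            summary_tbl$fraction_within_10s))
cat("solo transitions:", nrow(solo_trans), "\n")
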