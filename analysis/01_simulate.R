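#!/usr/bin/env Rscript
# Stage 1: generate the synthetic experiment standing in for the
# recordings: 6 birds, all 15 pairs, 4 sessions per pair, each session a
# 900 s PRE solo phase, a 900 s face-to-face (F2F) phase and a 900 s POST
# solo phase. Two birds call independently with heavy-tailed log10-normal
# gaps (~35 calls per solo phase) and answer each other in the F2F phase
# with probability 1/3 after a ~0.19 s log10-normal latency.

library(callexchange)

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

seed <- 1234L
sessions <- simulate_experiment(seed = seed)
events <- bind_session_events(sessions)
write_call_table(events, "scratch/simulated_calls.csv")

cat("sessions:", length(sessions), "\n")
cat("total calls:", nrow(events), "\n")
cat("calls per phase:\n")
print(table(events$phase))
cat("event table written to scratch/simulated_calls.csv (seed ", seed,
    ")\n", sep = "")
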