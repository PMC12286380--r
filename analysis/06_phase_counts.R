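#!/usr/bin/env Rscript
# Stage 6: does a bird call more when facing a partner? Count each
# subject's calls per phase and fit Poisson log-link mixed models with
# random intercepts for subject and trial; compare the phase model against
# the intercept-only null by AIC.

library(callexchange)
library(readr)

events <- read_call_table("scratch/simulated_calls.csv")
sessions <- callexchange:::sessions_from_events(events)
rows <- count_calls_by_phase(sessions)
write_csv(rows, "results/phase_counts.csv")

cat("mean calls per phase (subject birds):\n")
print(round(tapply(rows$n_calls, rows$phase, mean), 1))

phase_fit <- fit_count_model(rows, include_phase = TRUE)
null_fit <- fit_count_model(rows, include_phase = FALSE)
sel <- select_model_aic(list(phase_fit, null_fit))
write_csv(sel$delta_table, "results/count_model_aic.csv")

print(phase_fit)
print(sel$delta_table)
cat(sprintf("selected model: %s\n",
            if (sel$best$include_phase) "phase" else "null"))
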