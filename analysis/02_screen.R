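#!/usr/bin/env Rscript
# Item screening and scale-level descriptives on the simulated survey:
# Cronbach's alpha per scale, screening prevalence at the >= 5 cutoff,
# the SD-based low-informativeness rule, and the goldbricker-style
# redundancy screen. Run analysis/01_simulate.R first.

suppressMessages(library(symptomnet))

responses <- read_responses("results/simulated_responses.csv",
                            phq_gad_communities())

alpha <- vapply(c("depression", "anxiety"),
                function(s) cronbach_alpha(responses, s), numeric(1))
screen <- scale_screen(responses, cutoff = 5)
report <- screen_items(responses)

jsonlite::write_json(
  list(cronbach_alpha = as.list(alpha),
       prevalence = as.list(screen$prevalence),
       n_positive = as.list(screen$n_positive),
       excluded_low_sd = report$excluded_low_sd,
       redundant_pairs = report$redundant_pairs),
  "results/screening.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("Cronbach's alpha: depression %.3f, anxiety %.3f.\n",
            alpha["depression"], alpha["anxiety"]))
cat(sprintf("Screening positive (total >= 5): depression %.0f%%, anxiety %.0f%%.\n",
            100 * screen$prevalence["depression"],
            100 * screen$prevalence["anxiety"]))
cat(sprintf("SD rule excluded %d item(s); redundancy screen flagged %d pair(s).\n",
            length(report$excluded_low_sd), nrow(report$redundant_pairs)))
cat("Wrote results/screening.json.\n")
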