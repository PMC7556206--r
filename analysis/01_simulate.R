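#!/usr/bin/env Rscript
# Simulate the synthetic dual-pathology SEEG cohort.
#
# Two tiers are produced under results/:
#  - a full-size rate-table cohort (16 patients, 5/7/4 groups, 60 + 124
#    contacts, 1-h segments) exercising the statistics downstream, and
#  - a miniature signal-level patient (EDF + channel TSV + ground-truth CSV)
#    that 02_detect.R runs the detectors on.

suppressPackageStartupMessages(library(dualhfo))
dir.create("results/signals", showWarnings = FALSE, recursive = TRUE)

seed <- 20260930L

cfg <- sim_config(seed = seed)
sim <- simulate_rate_table(cfg)
write.csv(sim$rates, "results/rates.csv", row.names = FALSE)
write.csv(sim$groups, "results/cohort_true_groups.csv", row.names = FALSE)
cat(sprintf("rate-table cohort: %d patients, %d channels (%d hippocampal, %d neocortical)\n",
            nrow(sim$groups), nrow(sim$rates),
            sum(sim$rates$lesion == "hippocampal"),
            sum(sim$rates$lesion == "neocortical")))

# miniature signal-level patient: 2-min segment keeps synthesis fast while
# leaving enough events for the detectors to be worth scoring
sig_cfg <- sim_config(n_patients = 3, group_counts = c(1, 1, 1),
                      hip_total = 8, neo_total = 12, min_hip = 2, min_neo = 3,
                      segment_duration = 120, seed = seed + 1L)
spec <- generate_cohort(sig_cfg)[[1]]
rec <- simulate_recording(spec, sig_cfg)
paths <- write_recording(rec, "results/signals")
cat(sprintf("signal patient %s: %d channels x %d s, %d injected events -> %s\n",
            rec$patient_id, nrow(rec$signals),
            sig_cfg$segment_duration, nrow(rec$ground_truth),
            paths[["edf"]]))
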