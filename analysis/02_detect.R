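#!/usr/bin/env Rscript
# Detect interictal spikes, ripples, IES-ripples and fast ripples in the
# simulated signal patient from 01_simulate.R, score the detections against
# the injected ground truth, and write the event list.

suppressPackageStartupMessages(library(dualhfo))

edf <- "results/signals/P01.edf"
if (!file.exists(edf))
  stop("run analysis/01_simulate.R first (", edf, " not found)")

rec <- read_recording(edf, "results/signals/P01_channels.tsv")
cat(sprintf("loaded %s: %d channels @ %g Hz\n",
            rec$patient_id, nrow(rec$signals), rec$sampling_rate))

events <- detect_all(rec, detection_params())
write.csv(events, "results/events.csv", row.names = FALSE)
cat(sprintf("detected %d events (%s)\n", nrow(events),
            paste(names(table(events$event_type)),
                  table(events$event_type), sep = ": ", collapse = ", ")))

truth <- read.csv("results/signals/P01_events.csv")
truth <- data.frame(channel_id = truth$channel_id,
                    event_type = truth$event_type,
                    onset = truth$onset_s, duration = truth$duration_s)
scores <- evaluate_detection(events, truth)
write.csv(scores, "results/detection_scores.csv", row.names = FALSE)
print(scores)
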