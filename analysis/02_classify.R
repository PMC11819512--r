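#!/usr/bin/env Rscript
# Stage 2: filter candidate trains and classify social vs non-social.
#
# Applies the detector view filter (mean rate >= 100 c/s, 105-140 kHz,
# frames with >= 256 clicks) and then the social criteria (a)-(d), and
# scores the decisions against the simulation truth.

library(porpoisesocial)

out <- "results/analysis"
trains <- read_clicks(file.path(out, "clicks.csv"))
truth <- read_truth(file.path(out, "truth.csv"))
record_end <- 90 * 86400

frames <- frame_partition(trains, 0, record_end)
elig <- eligible_frames(frames)
cands <- candidate_view(trains, frames)
cat(sprintf("filter: %d/%d frames eligible, %d/%d trains in candidate view\n",
            nrow(elig), nrow(frames), length(cands), length(trains)))

cl <- classify(cands, elig, neighbors = trains)
write.csv(cl, file.path(out, "classifications.csv"), row.names = FALSE)

m <- classification_metrics(cl, truth)
cat(sprintf("classification vs truth: precision %.3f, recall %.3f (tp %d, fp %d, fn %d)\n",
            m["precision"], m["recall"], m["tp"], m["fp"], m["fn"]))

soc <- merge(cl[cl$decision == "social", ], truth, by = "train_id")
cat("pattern labels on true social trains:\n")
print(table(labelled = soc$pattern, truth = soc$true_pattern))
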