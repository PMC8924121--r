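#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic resting-state cohort.
#
# 25 participants x 4 five-minute rest epochs: continuous 1000-Hz ECG and
# skin-conductance recordings driven by a latent anxiety random walk, with
# per-epoch STAI-S and valence/arousal/dominance ratings. A small two-
# participant cohort is written out in full as CSV (signals included) under
# scratch/ to demonstrate the on-disk interchange format; the full cohort
# is re-created deterministically from the seed by the later stages instead
# of shipping ~60 M samples of CSV.

library(staitrack)

seed <- 1
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

demo <- simulate_cohort(n_participants = 2, epochs_per_participant = 4,
                        seed = seed, epoch_s = 60)
write_cohort_csv(demo, "scratch/demo_cohort", force = TRUE)
cat("Demo cohort written to scratch/demo_cohort (2 participants, 60-s epochs)\n")

cohort <- simulate_cohort(seed = seed, signals = FALSE)
write.csv(cohort$labels, "results/cohort_labels.csv", row.names = FALSE)
write.csv(cohort$truth, "results/cohort_ground_truth.csv", row.names = FALSE)
write.csv(cohort$schedule, "results/cohort_schedule.csv", row.names = FALSE)

cat(sprintf("Cohort design: %d participants, %d epochs each (%d rows)\n",
            length(unique(cohort$labels$participant)),
            max(cohort$labels$epoch_index), nrow(cohort$labels)))
cat(sprintf("STAI-S range: %.1f-%.1f; latent anxiety range: %.2f-%.2f\n",
            min(cohort$labels$stai_s), max(cohort$labels$stai_s),
            min(cohort$latent$anxiety), max(cohort$latent$anxiety)))
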