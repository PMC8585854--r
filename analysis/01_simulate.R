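#!/usr/bin/env Rscript
# Stage 1: simulate the default cohort (12 patients, 12 controls, both
# eyes, 4 check sizes x 2 reversal rates) and realize it as raw sweep
# recordings. Ground truth goes to results/, the bulky sweep archive to
# scratch/ (it is regenerated on demand and not a deliverable).

suppressPackageStartupMessages(library(pergss))

seed <- 20240501L
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

design <- cohort_design()
noise <- sweep_noise_model()
stopifnot(length(validate_config(run_config(seed, design, noise))) == 0)

truth <- generate_cohort_table(design, seed = seed)
write_cohort_csv(truth, "results/ground_truth.csv")

archive <- simulate_sweep_archive(truth, noise, n_sweeps = 10,
                                  seed = seed + 1L)
write_archive(archive, "scratch/sweep_archive")

cat(sprintf("simulated %d sweep blocks (%d subjects x 2 eyes x 8 conditions)\n",
            length(archive$blocks), 2 * design$n_per_group))
cat(sprintf("ground-truth amplitudes span %.2f-%.2f uV, response times %.1f-%.1f ms\n",
            min(truth$amplitude_uV), max(truth$amplitude_uV),
            min(truth$response_time_ms), max(truth$response_time_ms)))
cat("wrote results/ground_truth.csv and scratch/sweep_archive/\n")
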