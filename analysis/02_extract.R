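#!/usr/bin/env Rscript
# Stage 2: preprocess every sweep block (120 uV artifact rejection,
# stimulus-synchronized averaging, 40 Hz brick-wall low-pass, linear
# detrend) and read out the steady-state response at the reversal rate:
# noise-corrected amplitude, adjacent-bin noise, SNR, and the response
# time from the phase.

suppressPackageStartupMessages(library(pergss))

archive <- read_archive("scratch/sweep_archive")
cohort <- extract_cohort(archive, threshold_uV = 120, cutoff_hz = 40,
                         window_lo_ms = 30, noise_method = "linear")
write_cohort_csv(cohort, "results/cohort.csv")

truth <- read_cohort_csv("results/ground_truth.csv")
key <- function(d) paste(d$subject, d$eye, d$check_size_deg,
                         d$reversal_rate_rps)
m <- match(key(cohort), key(truth))
amp_err <- cohort$amplitude_uV - truth$amplitude_uV[m]
cat(sprintf("extracted %d records; %d sweeps rejected in total\n",
            nrow(cohort), sum(cohort$n_sweeps_rejected)))
cat(sprintf("median SNR %.1f; mean amplitude error vs ground truth %+.3f uV (sd %.3f)\n",
            median(cohort$snr), mean(amp_err), sd(amp_err)))
cat("wrote results/cohort.csv\n")
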