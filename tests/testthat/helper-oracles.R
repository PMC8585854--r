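# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (enumeration, brute-force step-down,
# direct projection) and never reuse the implementation under test.

# a noise model with every disturbance switched off
noiseless_model <- function(sampling_rate_hz = 500, sweep_length_s = 0.96) {
  sweep_noise_model(sampling_rate_hz, sweep_length_s,
                    white_noise_sd_uV = 0, drift_intercept_sd_uV = 0,
                    drift_slope_sd_uV = 0, artifact_rate = 0)
}

# bare trace wrapper for spectral tests
make_trace <- function(samples, fs = 500, sweep_length_s = 0.96,
                       condition = stimulus_condition(0.8, 12.5)) {
  structure(list(samples = samples, sampling_rate_hz = fs,
                 sweep_length_s = sweep_length_s, condition = condition,
                 n_sweeps_used = 1L, n_sweeps_rejected = 0L),
            class = "perg_trace")
}

time_axis <- function(fs = 500, sweep_length_s = 0.96) {
  (seq_len(round(fs * sweep_length_s)) - 1) / fs
}

# exact rank-sum p-value by full enumeration of all rank assignments
enum_rank_sum_p <- function(x, y, alternative) {
  nx <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(pooled), nx)
  w_all <- apply(splits, 2, function(idx)
    sum(r[idx]) - nx * (nx + 1) / 2)
  switch(alternative,
    less = mean(w_all <= w_obs),
    greater = mean(w_all >= w_obs),
    two.sided = min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))))
}

# brute-force Holm flags: literal step-down walk
brute_holm_flags <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  flags <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) flags[o[i]] <- TRUE else break
  }
  flags
}

# balanced 2-group x (p x q) repeated-measures table with iid noise
make_balanced <- function(n = 6, group_shift = 0, subj_sd = 0.4,
                          noise_sd = 0.5,
                          check_sizes = c(0.8, 1.6, 3.2, 16),
                          rates = c(12.5, 18.75), seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(2 * n))
  grp <- rep(c("control", "patient"), each = n)
  d <- expand.grid(subject = subj, check_size_deg = check_sizes,
                   reversal_rate_rps = rates, stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject, subj)]
  subj_eff <- rnorm(2 * n, 0, subj_sd)
  d$amplitude_uV <- 2 + subj_eff[match(d$subject, subj)] +
    ifelse(d$group == "patient", -group_shift, 0) +
    rnorm(nrow(d), 0, noise_sd)
  d
}

# split-plot oracle via base aov() with Error strata
aov_oracle <- function(d, dv = "amplitude_uV") {
  d$s <- factor(d$subject); d$g <- factor(d$group)
  d$cs <- factor(d$check_size_deg); d$fr <- factor(d$reversal_rate_rps)
  d$y <- d[[dv]]
  fit <- stats::aov(y ~ g * cs * fr + Error(s / (cs * fr)), data = d)
  summary(fit)
}

pull_aov <- function(sm, stratum, term) {
  tab <- sm[[stratum]][[1]]
  i <- match(term, trimws(rownames(tab)))
  list(ss = tab[i, "Sum Sq"], df = tab[i, "Df"], F = tab[i, "F value"],
       p = tab[i, "Pr(>F)"])
}
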