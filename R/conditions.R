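#' Stimulus condition for a steady-state PERG recording
#'
#' A single checkerboard-reversal condition, described by the check size
#' (side length of one check, degrees of visual angle) and the reversal
#' rate (reversals per second). For steady-state analysis the response is
#' read out at the reversal rate, so the reversal rate in rps equals the
#' analysis frequency in Hz.
#'
#' @param check_size_deg check size in degrees of visual angle (> 0).
#' @param reversal_rate_rps pattern reversal rate in reversals per second
#'   (> 0). Must hit an exact DFT bin for every sweep length in use:
#'   `reversal_rate_rps * sweep_length_s` must be an integer.
#' @param sweep_length_s sweep length(s) in seconds the condition must be
#'   bin-aligned with (default 0.96 s).
#' @return A list of class `"perg_condition"` with the two fields.
#' @examples
#' stimulus_condition(0.8, 12.5)   # bin 12 of a 0.96 s sweep
#' @export
stimulus_condition <- function(check_size_deg, reversal_rate_rps,
                               sweep_length_s = 0.96) {
  stopifnot(is.numeric(check_size_deg), length(check_size_deg) == 1L,
            check_size_deg > 0,
            is.numeric(reversal_rate_rps), length(reversal_rate_rps) == 1L,
            reversal_rate_rps > 0)
  for (Ts in sweep_length_s) {
    k <- reversal_rate_rps * Ts
    if (abs(k - round(k)) > 1e-9) {
      stop(sprintf(
        "reversal rate %g rps is not bin-aligned with a %g s sweep (%g cycles per sweep); nearest aligned rates are %g and %g rps",
        reversal_rate_rps, Ts, k, floor(k) / Ts, ceiling(k) / Ts))
    }
  }
  structure(list(check_size_deg = check_size_deg,
                 reversal_rate_rps = reversal_rate_rps),
            class = "perg_condition")
}

#' Default stimulus-condition grid
#'
#' The fully crossed grid of four check sizes (0.8, 1.6, 3.2, 16 degrees)
#' and two reversal rates (12.5 and 18.75 rps) used throughout the
#' package defaults.
#'
#' @param check_sizes_deg check sizes in degrees.
#' @param reversal_rates_rps reversal rates in rps.
#' @param sweep_length_s sweep length used for bin-alignment validation.
#' @return A list of `perg_condition` objects, frequency varying fastest
#'   within check size.
#' @export
default_conditions <- function(check_sizes_deg = c(0.8, 1.6, 3.2, 16),
                               reversal_rates_rps = c(12.5, 18.75),
                               sweep_length_s = 0.96) {
  out <- list()
  for (cs in check_sizes_deg) {
    for (rr in reversal_rates_rps) {
      out[[length(out) + 1L]] <- stimulus_condition(cs, rr, sweep_length_s)
    }
  }
  out
}

#' Sweep-level noise model
#'
#' Parameters of the additive disturbances applied to each simulated
#' sweep: white sample noise, a per-sweep affine baseline drift, and
#' occasional single-sample artifact spikes large enough to trip the
#' amplitude-threshold rejection rule.
#'
#' @param sampling_rate_hz ADC rate in Hz (default 500; 480 samples per
#'   0.96 s sweep).
#' @param sweep_length_s sweep length in seconds (default 0.96).
#' @param white_noise_sd_uV SD of iid Gaussian sample noise, in microvolts.
#' @param drift_intercept_sd_uV,drift_slope_sd_uV SDs of the per-sweep
#'   baseline offset (uV) and linear drift slope (uV per sweep duration);
#'   each sweep draws its own affine drift from centred normals.
#' @param artifact_rate probability that a sweep carries an artifact spike.
#' @param artifact_amplitude_uV spike amplitude in uV; the default 200
#'   exceeds the 120 uV rejection threshold so injected artifacts are
#'   rejectable.
#' @return A list of class `"perg_noise_model"`.
#' @export
sweep_noise_model <- function(sampling_rate_hz = 500,
                              sweep_length_s = 0.96,
                              white_noise_sd_uV = 1.5,
                              drift_intercept_sd_uV = 2,
                              drift_slope_sd_uV = 2,
                              artifact_rate = 0.05,
                              artifact_amplitude_uV = 200) {
  n <- sampling_rate_hz * sweep_length_s
  if (abs(n - round(n)) > 1e-9) {
    stop("sampling_rate_hz * sweep_length_s must be an integer number of samples")
  }
  stopifnot(artifact_rate >= 0, artifact_rate <= 1,
            white_noise_sd_uV >= 0, drift_intercept_sd_uV >= 0,
            drift_slope_sd_uV >= 0, artifact_amplitude_uV >= 0)
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 sweep_length_s = sweep_length_s,
                 white_noise_sd_uV = white_noise_sd_uV,
                 drift_intercept_sd_uV = drift_intercept_sd_uV,
                 drift_slope_sd_uV = drift_slope_sd_uV,
                 artifact_rate = artifact_rate,
                 artifact_amplitude_uV = artifact_amplitude_uV),
            class = "perg_noise_model")
}

#' Published group-level PERG summary statistics
#'
#' Group means, standard deviations, estimated-marginal-mean differences
#' with their (constant) standard error, uncorrected post-hoc p-values and
#' Hedges-corrected effect sizes from a published steady-state PERG study
#' of major depression (12 patients, 12 matched controls, 4 check sizes x
#' 2 reversal rates). These printed summaries parameterize the default
#' synthetic cohort and serve as worked-example inputs: the effect sizes
#' and the Holm significance pattern are recomputable from the other
#' columns.
#'
#' The `p_uncorrected` entry of 1e-4 in the response-time table is an
#' upper bound (printed as "< 0.0001").
#'
#' @return A list with two data frames, `amplitude` (uV) and `time` (ms),
#'   one row per check size x reversal rate condition. Columns:
#'   `check_size_deg`, `reversal_rate_rps`, `mean_control`, `sd_control`,
#'   `mean_patient`, `sd_patient`, `emm_diff`, `emm_se`, `p_uncorrected`,
#'   `holm_significant`, `hedges_g`, plus `n_control` / `n_patient`.
#' @export
mdd_perg_summary <- function() {
  amp <- data.frame(
    check_size_deg    = c(0.8, 1.6, 3.2, 16, 0.8, 1.6, 3.2, 16),
    reversal_rate_rps = c(rep(12.5, 4), rep(18.75, 4)),
    mean_control = c(2.9, 2.5, 2.3, 2.3, 2.5, 2.2, 2.1, 2.2),
    sd_control   = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.4, 0.4, 0.5),
    mean_patient = c(2.3, 2.0, 1.8, 1.8, 1.9, 1.7, 1.6, 1.8),
    sd_patient   = c(0.7, 0.6, 0.5, 0.5, 0.7, 0.5, 0.5, 0.5),
    emm_diff = c(0.621, 0.549, 0.553, 0.490, 0.630, 0.514, 0.431, 0.331),
    emm_se   = rep(0.21, 8),
    p_uncorrected = c(0.007, 0.015, 0.014, 0.028, 0.006, 0.022, 0.051, 0.127),
    holm_significant = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    hedges_g = c(0.98, 1.00, 1.13, 0.95, 1.04, 1.03, 0.95, 0.67)
  )
  tim <- data.frame(
    check_size_deg    = c(0.8, 1.6, 3.2, 16, 0.8, 1.6, 3.2, 16),
    reversal_rate_rps = c(rep(12.5, 4), rep(18.75, 4)),
    mean_control = c(55.2, 51.7, 48.9, 44.7, 56.4, 53.4, 50.4, 46.5),
    sd_control   = c(2.9, 2.6, 2.2, 2.1, 1.8, 2.0, 2.1, 2.1),
    mean_patient = c(51.9, 48.3, 45.3, 41.5, 53.2, 49.6, 46.5, 43.0),
    sd_patient   = c(3.0, 2.8, 2.4, 2.4, 2.5, 2.3, 2.0, 1.8),
    emm_diff = c(3.37, 3.42, 3.58, 3.22, 3.19, 3.79, 3.87, 3.52),
    emm_se   = rep(0.96, 8),
    p_uncorrected = c(0.002, 0.001, 0.001, 0.002, 0.003, 0.001, 1e-4, 0.001),
    holm_significant = rep(TRUE, 8),
    hedges_g = c(1.09, 1.22, 1.53, 1.36, 1.41, 1.69, 1.84, 1.72)
  )
  amp$n_control <- 12L; amp$n_patient <- 12L
  tim$n_control <- 12L; tim$n_patient <- 12L
  list(amplitude = amp, time = tim)
}

#' Cohort design for the synthetic generator
#'
#' Describes the two-group, two-eye, fully crossed repeated-measures
#' design the generator draws from. Each group x condition cell has a
#' mean and a total between-subject SD for both the amplitude (uV) and
#' the response time (ms); within-subject correlation across conditions
#' is induced by one additive subject random effect shared by all cells,
#' and eye-level measurement jitter sits on top. The default models are
#' populated from the published summary tables (see
#' [mdd_perg_summary()]).
#'
#' The per-cell residual SD used when sampling is
#' `sqrt(max(sd_total^2 - subject_sd^2, min_cell_var))`, so the marginal
#' between-subject SD of an eye-averaged cell approximately reproduces
#' the configured total SD.
#'
#' @param n_per_group subjects per group (default 12).
#' @param groups group labels; first is the reference group.
#' @param eyes eye labels.
#' @param conditions list of [stimulus_condition()] objects.
#' @param amplitude_model,time_model data frames with columns
#'   `check_size_deg`, `reversal_rate_rps`, and per-group `mean_<group>`,
#'   `sd_<group>` columns (defaults built from [mdd_perg_summary()]).
#' @param amp_subject_sd_uV,time_subject_sd_ms SD of the shared subject
#'   random effect (defaults 0.3 uV, 1.5 ms).
#' @param amp_eye_sd_uV,time_eye_sd_ms SD of eye-level jitter
#'   (defaults 0.2 uV, 1 ms).
#' @param amp_floor_uV floor applied to sampled amplitudes (magnitudes
#'   cannot be negative; default 0.05 uV).
#' @return A list of class `"perg_cohort_design"`.
#' @export
cohort_design <- function(n_per_group = 12,
                          groups = c("control", "patient"),
                          eyes = c("left", "right"),
                          conditions = default_conditions(),
                          amplitude_model = NULL,
                          time_model = NULL,
                          amp_subject_sd_uV = 0.3,
                          time_subject_sd_ms = 1.5,
                          amp_eye_sd_uV = 0.2,
                          time_eye_sd_ms = 1.0,
                          amp_floor_uV = 0.05) {
  stopifnot(n_per_group >= 1, length(groups) == 2, length(eyes) >= 1,
            length(conditions) >= 1,
            amp_subject_sd_uV >= 0, time_subject_sd_ms >= 0,
            amp_eye_sd_uV >= 0, time_eye_sd_ms >= 0, amp_floor_uV > 0)
  ref <- mdd_perg_summary()
  if (is.null(amplitude_model)) {
    amplitude_model <- .model_from_summary(ref$amplitude, groups)
  }
  if (is.null(time_model)) {
    time_model <- .model_from_summary(ref$time, groups)
  }
  for (m in list(amplitude_model, time_model)) {
    .check_model_coverage(m, groups, conditions)
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 eyes = eyes, conditions = conditions,
                 amplitude_model = amplitude_model, time_model = time_model,
                 amp_subject_sd_uV = amp_subject_sd_uV,
                 time_subject_sd_ms = time_subject_sd_ms,
                 amp_eye_sd_uV = amp_eye_sd_uV,
                 time_eye_sd_ms = time_eye_sd_ms,
                 amp_floor_uV = amp_floor_uV),
            class = "perg_cohort_design")
}

# reshape a printed summary table into the generator's mean/sd-per-group form
.model_from_summary <- function(tab, groups) {
  m <- tab[, c("check_size_deg", "reversal_rate_rps")]
  m[[paste0("mean_", groups[1])]] <- tab$mean_control
  m[[paste0("sd_", groups[1])]] <- tab$sd_control
  m[[paste0("mean_", groups[2])]] <- tab$mean_patient
  m[[paste0("sd_", groups[2])]] <- tab$sd_patient
  m
}

.check_model_coverage <- function(model, groups, conditions) {
  need <- c("check_size_deg", "reversal_rate_rps",
            paste0("mean_", groups), paste0("sd_", groups))
  miss <- setdiff(need, names(model))
  if (length(miss)) stop("model is missing columns: ", paste(miss, collapse = ", "))
  for (cond in conditions) {
    row <- .model_row(model, cond)
    if (is.null(row)) {
      stop(sprintf("model has no row for condition %g deg / %g rps",
                   cond$check_size_deg, cond$reversal_rate_rps))
    }
    for (g in groups) {
      if (row[[paste0("mean_", g)]] <= 0) stop("model means must be > 0")
      if (row[[paste0("sd_", g)]] < 0) stop("model SDs must be >= 0")
    }
  }
  invisible(model)
}

.model_row <- function(model, cond) {
  i <- which(abs(model$check_size_deg - cond$check_size_deg) < 1e-9 &
             abs(model$reversal_rate_rps - cond$reversal_rate_rps) < 1e-9)
  if (length(i) != 1L) return(NULL)
  model[i, , drop = FALSE]
}
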