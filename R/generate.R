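# Synthetic cohort and sweep generation.
#
# Two levels: (1) a cohort table of per-subject, per-eye, per-condition
# ground-truth amplitudes and response times drawn from the design's
# group models; (2) raw sweep waveforms realizing a given amplitude and
# response time as a single sinusoid at the reversal rate plus affine
# drift, white noise and occasional artifact spikes.

# run expr with a temporarily seeded RNG, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.wrap_phase <- function(x) {
  w <- x %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' Generate a ground-truth cohort table
#'
#' Draws per-subject, per-eye, per-condition true amplitudes and response
#' times from the design's group models. Each eye-level amplitude is
#' `max(floor, cell mean + subject effect + cell deviate + eye jitter)`,
#' where the subject effect is shared across all cells of a subject
#' (inducing within-subject correlation), the cell deviate is shared by
#' both eyes, and the eye jitter is independent per eye. Response times
#' are built the same way (without the floor semantics of a magnitude;
#' they are kept positive by construction of the default models).
#'
#' @param design a [cohort_design()].
#' @param seed integer seed; identical seed and design give an identical
#'   table.
#' @return A data frame with one row per subject x eye x condition:
#'   `subject`, `group`, `eye`, `check_size_deg`, `reversal_rate_rps`,
#'   `amplitude_uV`, `response_time_ms`. The configured group x condition
#'   means are attached as attribute `"truth"`.
#' @export
generate_cohort_table <- function(design, seed = NULL) {
  stopifnot(inherits(design, "perg_cohort_design"))
  .with_seed(seed, {
    n <- design$n_per_group
    n_eyes <- length(design$eyes)
    pieces <- vector("list", length(design$groups))
    truth <- list()
    for (gi in seq_along(design$groups)) {
      g <- design$groups[gi]
      subj <- sprintf("%s_%02d", substr(g, 1, 3), seq_len(n))
      subj_amp <- stats::rnorm(n, 0, design$amp_subject_sd_uV)
      subj_tim <- stats::rnorm(n, 0, design$time_subject_sd_ms)
      cond_pieces <- vector("list", length(design$conditions))
      for (ci in seq_along(design$conditions)) {
        cond <- design$conditions[[ci]]
        arow <- .model_row(design$amplitude_model, cond)
        trow <- .model_row(design$time_model, cond)
        amp_mu <- arow[[paste0("mean_", g)]]
        tim_mu <- trow[[paste0("mean_", g)]]
        amp_cell_sd <- sqrt(max(arow[[paste0("sd_", g)]]^2 -
                                  design$amp_subject_sd_uV^2, 1e-4))
        tim_cell_sd <- sqrt(max(trow[[paste0("sd_", g)]]^2 -
                                  design$time_subject_sd_ms^2, 1e-4))
        amp_cell <- stats::rnorm(n, 0, amp_cell_sd)
        tim_cell <- stats::rnorm(n, 0, tim_cell_sd)
        amp_eye <- matrix(stats::rnorm(n * n_eyes, 0, design$amp_eye_sd_uV),
                          n, n_eyes)
        tim_eye <- matrix(stats::rnorm(n * n_eyes, 0, design$time_eye_sd_ms),
                          n, n_eyes)
        amp <- pmax(design$amp_floor_uV,
                    amp_mu + subj_amp + amp_cell + amp_eye)
        tim <- tim_mu + subj_tim + tim_cell + tim_eye
        cond_pieces[[ci]] <- data.frame(
          subject = rep(subj, n_eyes), group = g,
          eye = rep(design$eyes, each = n),
          check_size_deg = cond$check_size_deg,
          reversal_rate_rps = cond$reversal_rate_rps,
          amplitude_uV = as.vector(amp),
          response_time_ms = as.vector(tim))
        truth[[length(truth) + 1L]] <- data.frame(
          group = g, check_size_deg = cond$check_size_deg,
          reversal_rate_rps = cond$reversal_rate_rps,
          amplitude_uV = amp_mu, response_time_ms = tim_mu)
      }
      pieces[[gi]] <- do.call(rbind, cond_pieces)
    }
    out <- do.call(rbind, pieces)
    out <- out[order(out$group, out$subject, out$reversal_rate_rps,
                     out$check_size_deg, out$eye), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}

#' Generate one block of raw PERG sweeps
#'
#' Each sweep is a single sinusoid at the reversal rate,
#' `A * sin(2*pi*f*t + phi)` with `phi = -2*pi*f*response_time_ms/1000`
#' wrapped to (-pi, pi], plus an affine baseline drift, iid white noise,
#' and (with probability `noise$artifact_rate`) a single-sample artifact
#' spike of `+/- noise$artifact_amplitude_uV` at a uniform-random
#' position. With all noise terms zero the downstream Fourier analysis
#' recovers the amplitude and the response time (modulo the stimulus
#' period) exactly.
#'
#' @param amplitude_uV peak amplitude of the fundamental, uV (>= 0).
#' @param response_time_ms steady-state response latency, ms.
#' @param condition a [stimulus_condition()].
#' @param noise a [sweep_noise_model()].
#' @param n_sweeps number of sweeps (>= 1).
#' @param seed optional integer seed.
#' @param subject_id,group,eye metadata labels carried on the block.
#' @return A list of class `"perg_sweep_block"`: metadata fields plus
#'   `sweeps`, an `n_sweeps x n_samples` matrix in uV.
#' @export
generate_sweep_block <- function(amplitude_uV, response_time_ms, condition,
                                 noise = sweep_noise_model(), n_sweeps = 10,
                                 seed = NULL, subject_id = "s01",
                                 group = "control", eye = "left") {
  stopifnot(amplitude_uV >= 0, n_sweeps >= 1,
            inherits(condition, "perg_condition"),
            inherits(noise, "perg_noise_model"))
  n <- noise$sampling_rate_hz * noise$sweep_length_s
  if (abs(n - round(n)) > 1e-9) stop("non-integer samples per sweep")
  n <- as.integer(round(n))
  f <- condition$reversal_rate_rps
  t_axis <- (seq_len(n) - 1L) / noise$sampling_rate_hz
  phi <- .wrap_phase(-2 * pi * f * response_time_ms / 1000)
  base <- amplitude_uV * sin(2 * pi * f * t_axis + phi)
  .with_seed(seed, {
    sweeps <- matrix(0, nrow = n_sweeps, ncol = n)
    for (i in seq_len(n_sweeps)) {
      a <- stats::rnorm(1, 0, noise$drift_intercept_sd_uV)
      b <- stats::rnorm(1, 0, noise$drift_slope_sd_uV)
      sw <- base + a + b * (t_axis / noise$sweep_length_s) +
        stats::rnorm(n, 0, noise$white_noise_sd_uV)
      if (noise$artifact_rate > 0 &&
          stats::runif(1) < noise$artifact_rate) {
        pos <- sample.int(n, 1)
        sw[pos] <- sw[pos] +
          sample(c(-1, 1), 1) * noise$artifact_amplitude_uV
      }
      sweeps[i, ] <- sw
    }
    new_sweep_block(subject_id, group, eye, condition,
                    noise$sampling_rate_hz, noise$sweep_length_s, sweeps)
  })
}

#' Simulate a full sweep archive for a cohort
#'
#' Realizes every row of a ground-truth cohort table as a block of raw
#' sweeps, giving a complete synthetic recording session.
#'
#' @param cohort_table output of [generate_cohort_table()].
#' @param noise a [sweep_noise_model()].
#' @param n_sweeps sweeps per block.
#' @param seed integer seed; per-block seeds are derived from it.
#' @param sweep_length_s sweep length used to validate bin alignment.
#' @return A `perg_sweep_archive` (see [sweep_archive()]).
#' @export
simulate_sweep_archive <- function(cohort_table, noise = sweep_noise_model(),
                                   n_sweeps = 10, seed = NULL) {
  blocks <- vector("list", nrow(cohort_table))
  .with_seed(seed, {
    for (i in seq_len(nrow(cohort_table))) {
      r <- cohort_table[i, ]
      cond <- stimulus_condition(r$check_size_deg, r$reversal_rate_rps,
                                 noise$sweep_length_s)
      blocks[[i]] <- generate_sweep_block(
        r$amplitude_uV, r$response_time_ms, cond, noise, n_sweeps,
        seed = NULL, subject_id = r$subject, group = r$group, eye = r$eye)
    }
  })
  sweep_archive(blocks)
}
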