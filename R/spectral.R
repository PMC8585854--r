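# Frequency-domain readout of the steady-state response: amplitude and
# phase at the reversal-rate bin, adjacent-bin noise estimate,
# noise-corrected amplitude, SNR.
#
# Amplitude convention: peak amplitude of the fundamental, 2*|X_k|/N in
# uV, the magnitude a steady-state ERG report quotes. Phase convention:
# the phase of an equivalent sine, i.e. the value phi such that the
# trace contains A*sin(2*pi*f*t + phi); this makes the generator's
# response times round-trip through the timing module.

.trace_bin <- function(trace, frequency_hz) {
  n <- length(trace$samples)
  k <- frequency_hz * trace$sweep_length_s
  if (abs(k - round(k)) > 1e-9) {
    lo <- floor(k) / trace$sweep_length_s
    hi <- ceiling(k) / trace$sweep_length_s
    stop(sprintf(
      "%g Hz is not bin-aligned with a %g s sweep; nearest bins are %g and %g Hz",
      frequency_hz, trace$sweep_length_s, lo, hi))
  }
  k <- as.integer(round(k))
  if (k < 1 || k >= n / 2) {
    stop(sprintf("bin %d outside the analyzable range [1, %d)", k, n %/% 2))
  }
  k
}

.bin_amplitude <- function(X, k, n) 2 * Mod(X[k + 1]) / n

#' Complex Fourier component at a bin-aligned frequency
#'
#' Computes the DFT component at the requested frequency, returning the
#' peak amplitude `2*|X_k|/N` in uV and the phase of the equivalent sine
#' in (-pi, pi]. Exact for bin-aligned sinusoids: a trace
#' `A*sin(2*pi*f*t + phi)` returns amplitude `A` and phase `phi`.
#'
#' @param trace a `perg_trace`.
#' @param frequency_hz analysis frequency; `frequency_hz * sweep_length_s`
#'   must be an integer k with 1 <= k < N/2.
#' @return A list: `amplitude_uV`, `phase_rad`, `bin_index`.
#' @export
fourier_component <- function(trace, frequency_hz) {
  stopifnot(inherits(trace, "perg_trace"))
  k <- .trace_bin(trace, frequency_hz)
  n <- length(trace$samples)
  Xk <- stats::fft(trace$samples)[k + 1]
  amp <- 2 * Mod(Xk) / n
  phase <- if (amp < 1e-12) 0 else .wrap_phase(Arg(Xk) + pi / 2)
  list(amplitude_uV = amp, phase_rad = phase, bin_index = k)
}

#' Adjacent-bin noise estimate
#'
#' The arithmetic mean of the spectral amplitudes (same 2/N peak
#' convention) at the two bins directly adjacent to the analysis bin.
#' Because the response is confined to its exact bin, the neighbours
#' carry only background noise.
#'
#' @inheritParams fourier_component
#' @return Noise estimate in uV.
#' @export
noise_estimate <- function(trace, frequency_hz) {
  stopifnot(inherits(trace, "perg_trace"))
  k <- .trace_bin(trace, frequency_hz)
  if (k - 1 < 1) stop("adjacent bin would be DC; frequency too low")
  n <- length(trace$samples)
  X <- stats::fft(trace$samples)
  mean(c(.bin_amplitude(X, k - 1, n), .bin_amplitude(X, k + 1, n)))
}

#' Noise-corrected amplitude
#'
#' `"linear"` (default) subtracts the noise magnitude from the signal
#' magnitude, floored at zero; `"power"` subtracts in power,
#' `sqrt(max(0, A^2 - N^2))`.
#'
#' @param amplitude_uV,noise_uV non-negative magnitudes in uV.
#' @param method `"linear"` or `"power"`.
#' @return Corrected amplitude in uV, in `[0, amplitude_uV]`.
#' @export
noise_correct <- function(amplitude_uV, noise_uV,
                          method = c("linear", "power")) {
  stopifnot(all(amplitude_uV >= 0), all(noise_uV >= 0))
  method <- match.arg(method)
  switch(method,
    linear = pmax(0, amplitude_uV - noise_uV),
    power = sqrt(pmax(0, amplitude_uV^2 - noise_uV^2)))
}

#' Signal-to-noise ratio
#'
#' Plain amplitude-over-noise ratio. A zero noise estimate with a
#' positive amplitude returns `Inf`; a zero amplitude returns 0
#' regardless of noise.
#'
#' @param amplitude_uV,noise_uV magnitudes in uV, `noise_uV >= 0`.
#' @return Dimensionless ratio.
#' @export
snr <- function(amplitude_uV, noise_uV) {
  stopifnot(all(noise_uV >= 0))
  ifelse(amplitude_uV == 0, 0, amplitude_uV / noise_uV)
}

#' Complete spectral readout at one frequency
#'
#' Convenience wrapper combining [fourier_component()],
#' [noise_estimate()], [noise_correct()] and [snr()].
#'
#' @inheritParams fourier_component
#' @param method noise-correction method, see [noise_correct()].
#' @return A list: `frequency_hz`, `bin_index`, `amplitude_uV`,
#'   `phase_rad`, `noise_uV`, `corrected_amplitude_uV`, `snr`.
#' @export
spectral_component <- function(trace, frequency_hz,
                               method = c("linear", "power")) {
  method <- match.arg(method)
  fc <- fourier_component(trace, frequency_hz)
  nz <- noise_estimate(trace, frequency_hz)
  list(frequency_hz = frequency_hz, bin_index = fc$bin_index,
       amplitude_uV = fc$amplitude_uV, phase_rad = fc$phase_rad,
       noise_uV = nz,
       corrected_amplitude_uV = noise_correct(fc$amplitude_uV, nz, method),
       snr = snr(fc$amplitude_uV, nz))
}
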