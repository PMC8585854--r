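# Phase-to-latency conversion for steady-state responses.
#
# The phase of the fundamental determines the response latency only up
# to whole stimulus periods (80 ms at 12.5 rps, 53.33 ms at 18.75 rps).
# The ambiguity is resolved by a configurable physiological window: the
# unique representative t0 + k*period inside [window_lo, window_lo +
# period) is reported. The default lower bound of 30 ms comfortably
# brackets observed steady-state PERG latencies (roughly 40-57 ms) for
# both reversal rates.

#' Convert extracted phase to a response time
#'
#' Uses the sine-phase convention of [fourier_component()]: a response
#' generated with latency `t` carries phase `-2*pi*f*t/1000`, so the
#' base delay is `((-phase) mod 2*pi) / (2*pi*f) * 1000` ms and the
#' reported time is the unique `t0 + k * period` inside
#' `[window_lo_ms, window_lo_ms + period)`. Adding any multiple of
#' 2*pi to the phase leaves the result unchanged.
#'
#' @param phase_rad extracted phase in radians.
#' @param frequency_hz stimulation (analysis) frequency, > 0.
#' @param window_lo_ms lower bound of the latency window, ms.
#' @return A list: `time_ms`, `cycles_added` (the integer k),
#'   `window_lo_ms`, `period_ms`.
#' @export
phase_to_response_time <- function(phase_rad, frequency_hz,
                                   window_lo_ms = 30) {
  stopifnot(frequency_hz > 0, is.finite(phase_rad))
  period_ms <- 1000 / frequency_hz
  t0 <- ((-phase_rad) %% (2 * pi)) / (2 * pi * frequency_hz) * 1000
  k <- ceiling((window_lo_ms - t0) / period_ms - 1e-12)
  time_ms <- t0 + k * period_ms
  # guard against edge rounding: enforce the half-open window exactly
  if (time_ms < window_lo_ms) { k <- k + 1L; time_ms <- t0 + k * period_ms }
  if (time_ms >= window_lo_ms + period_ms) {
    k <- k - 1L; time_ms <- t0 + k * period_ms
  }
  list(time_ms = time_ms, cycles_added = as.integer(k),
       window_lo_ms = window_lo_ms, period_ms = period_ms)
}
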