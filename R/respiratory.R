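# Analytic Morlet continuous wavelet transform (FFT implementation).
#
# omega0 = 6 (standard trade-off between time and frequency resolution);
# scale s relates to Fourier frequency f by s = (omega0 + sqrt(2 + omega0^2))
# / (4 * pi * f). With the sqrt(2 * pi * s / dt) normalization the expected
# squared modulus for white noise is flat across scales, which is what the
# spectral-concentration test below relies on.
morlet_cwt <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  x <- x - mean(x)
  xhat <- stats::fft(x)
  dt <- 1 / fs
  omega <- 2 * pi * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * dt)
  scales <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs)
  W <- matrix(0 + 0i, nrow = length(freqs), ncol = n)
  for (k in seq_along(scales)) {
    s <- scales[k]
    psi_hat <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    W[k, ] <- stats::fft(xhat * psi_hat, inverse = TRUE) / n
  }
  list(W = W, freqs = freqs, scales = scales)
}

#' Detect respiratory cycles by wavelet ridge analysis
#'
#' The respiratory-band-dominant source signal is analyzed with an analytic
#' Morlet continuous wavelet transform over `band`; the ridge (frequency of
#' maximum time-averaged power) gives the dominant respiratory frequency.
#' The signal is then band-passed around the ridge and cycle boundaries are
#' placed at successive troughs of the filtered signal (local minima with
#' minimum separation `1 / (1.5 * f_ridge)` seconds). Cycles run
#' trough-to-trough; partial cycles at the segment edges are discarded.
#'
#' A no-respiration error is raised when no frequency dominates the band:
#' the fraction of band power concentrated within +/- 25 percent of the
#' ridge must exceed `concentration_min` (white noise spreads its power
#' over the whole band and fails this).
#'
#' @param resp_source A `channel_recording`, e.g. from
#'   [derive_respiratory_signal()].
#' @param band `c(low, high)` search band in Hz; the default 0.08-0.6 Hz
#'   spans 4.8-36 breaths/min.
#' @param concentration_min Minimum fraction of band power within the ridge
#'   neighbourhood.
#' @param work_rate Internal analysis rate in Hz.
#' @return A data.frame of class `resp_cycles`, one row per complete cycle:
#'   `start`, `end`, `duration`, `resp_rate` (breaths/min,
#'   `= 60 / duration`).
#' @export
detect_respiratory_cycles <- function(resp_source, band = c(0.08, 0.6),
                                      concentration_min = 0.4,
                                      work_rate = 10) {
  stopifnot(inherits(resp_source, "channel_recording"))
  ch <- if (resp_source$rate > work_rate)
    resample_channel(resp_source, work_rate) else resp_source
  x <- ch$samples; fs <- ch$rate
  if (stats::sd(x) < 1e-12)
    stop("no respiration: source signal is flat")
  freqs <- exp(seq(log(band[1]), log(band[2]), length.out = 36L))
  cw <- morlet_cwt(x, fs, freqs)
  # time-average power away from the edges (crude cone-of-influence trim)
  trim <- min(floor(length(x) / 4), ceiling(2 * fs))
  idx <- (trim + 1):(length(x) - trim)
  P <- rowMeans(Mod(cw$W[, idx, drop = FALSE])^2)
  f_ridge <- freqs[which.max(P)]
  near <- freqs >= 0.75 * f_ridge & freqs <= 1.25 * f_ridge
  conc <- sum(P[near]) / sum(P)
  if (!is.finite(conc) || conc < concentration_min)
    stop(sprintf(paste0("no respiration: no dominant frequency in band ",
                        "(concentration %.2f < %.2f)"), conc, concentration_min))
  y <- bandpass(x, fs, c(0.5 * f_ridge, min(2 * f_ridge, 0.95 * fs / 2)),
                order = 2L, pad = round(fs * 2 / f_ridge))
  min_sep <- max(1L, round(fs / (1.5 * f_ridge)))
  tr <- local_minima(y, min_sep = min_sep)
  tr <- tr[tr > 1L & tr < length(y)]
  if (length(tr) < 2L)
    stop("no respiration: fewer than two troughs found")
  t_tr <- ch$t0 + (tr - 1) / fs
  out <- data.frame(start = t_tr[-length(t_tr)], end = t_tr[-1L])
  out$duration <- out$end - out$start
  out$resp_rate <- 60 / out$duration
  class(out) <- c("resp_cycles", "data.frame")
  out
}

#' Derive a respiratory surrogate signal from a dataset
#'
#' No airflow is recorded in this protocol, so a respiratory-band-dominant
#' surrogate is derived, in priority order: (1) low-pass-filtered CVP (its
#' respiratory swings dominate under airway-pressure interventions),
#' (2) low-pass-filtered PPG baseline, (3) cubic interpolation of the
#' per-beat pulse-pressure series. The chosen source is recorded in the
#' `"resp_source"` attribute.
#'
#' @param dataset A `sync_dataset`.
#' @param beats Optional [beat_table()] output; required for the
#'   pulse-pressure fallback.
#' @param cutoff Low-pass cutoff in Hz isolating the respiratory band.
#' @param work_rate Output rate in Hz.
#' @return A `channel_recording` labelled `"resp"` with attribute
#'   `resp_source` one of `"cvp"`, `"ppg"`, `"pp_series"`.
#' @export
derive_respiratory_signal <- function(dataset, beats = NULL, cutoff = 0.7,
                                      work_rate = 10) {
  stopifnot(inherits(dataset, "sync_dataset"))
  if (!is.null(dataset$channels$cvp)) {
    ch <- resample_channel(dataset$channels$cvp, work_rate)
    src <- "cvp"
  } else if (!is.null(dataset$channels$ppg)) {
    ch <- resample_channel(dataset$channels$ppg, work_rate)
    src <- "ppg"
  } else if (!is.null(beats) && nrow(beats) >= 4L &&
             any(is.finite(beats$pulse_pressure))) {
    ok <- is.finite(beats$pulse_pressure)
    t_out <- seq(min(beats$r_time[ok]), max(beats$r_time[ok]),
                 by = 1 / work_rate)
    y <- stats::spline(beats$r_time[ok], beats$pulse_pressure[ok],
                       xout = t_out, method = "natural")$y
    ch <- channel_recording(y, rate = work_rate, label = "resp",
                            units = "mmHg", t0 = t_out[1L])
    src <- "pp_series"
  } else {
    stop("no channel suitable as a respiratory surrogate (need cvp, ppg, or beats)")
  }
  y <- lowpass(ch$samples, ch$rate, cutoff = cutoff, order = 4L,
               pad = round(ch$rate * 10))
  out <- channel_recording(y, rate = ch$rate, label = "resp",
                           units = ch$units, t0 = ch$t0)
  attr(out, "resp_source") <- src
  out
}

#' Assign beats to respiratory cycles
#'
#' A beat belongs to the cycle whose half-open interval `[start, end)`
#' contains its R time; a beat exactly on a boundary belongs to the later
#' cycle. Beats outside all cycles get `NA`.
#'
#' @param beats A [beat_table()] data.frame.
#' @param cycles A [detect_respiratory_cycles()] data.frame.
#' @return `beats` with an added integer column `cycle`.
#' @export
assign_beats_to_cycles <- function(beats, cycles) {
  if (nrow(cycles) == 0L) {
    beats$cycle <- NA_integer_
    return(beats)
  }
  idx <- findInterval(beats$r_time, cycles$start)
  inside <- idx >= 1L & beats$r_time < cycles$end[pmax(idx, 1L)]
  beats$cycle <- ifelse(inside, idx, NA_integer_)
  beats
}
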