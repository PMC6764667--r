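#' Detect R peaks in an ECG channel
#'
#' Standard energy-based detector: zero-phase band-pass 5-30 Hz, squared
#' derivative, 150 ms moving-window integration, adaptive threshold
#' (rolling median of the integrated signal times a factor, with a small
#' global floor), 250 ms refractory period, and apex refinement on the raw
#' ECG within +/- 100 ms of each detection.
#'
#' @param ecg A `channel_recording` of at least 2 s.
#' @param refractory Minimum R-R interval in seconds.
#' @param threshold_factor Multiplier on the rolling median.
#' @return Strictly increasing numeric vector of R-peak times (seconds, on
#'   the channel's clock).
#' @export
detect_r_peaks <- function(ecg, refractory = 0.25, threshold_factor = 8) {
  stopifnot(inherits(ecg, "channel_recording"))
  x <- ecg$samples; fs <- ecg$rate
  if ((length(x) - 1) / fs < 2) stop("ECG must be at least 2 s long")
  if (diff(range(x)) < 1e-8 || stats::sd(x) < 1e-10)
    stop("no signal: ECG is flat or near-flat")
  hi <- min(30, 0.45 * fs)
  xf <- bandpass(x, fs, c(5, hi), order = 2L)
  d2 <- c(0, diff(xf))^2
  w <- max(3L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(d2, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  k <- round(2 * fs); if (k %% 2 == 0) k <- k + 1L
  k <- min(k, length(integ) - (1 - length(integ) %% 2))
  roll_med <- stats::runmed(integ, k, endrule = "median")
  thr <- pmax(threshold_factor * roll_med, 0.05 * max(integ))
  cand <- local_maxima(integ, min_sep = max(1L, round(refractory * fs)))
  cand <- cand[integ[cand] > thr[cand]]
  if (!length(cand)) stop("no signal: no QRS complexes detected")
  # refine each detection to the raw-ECG apex nearby
  half <- round(0.1 * fs)
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi2 <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi2]) - 1L)
  }, 0L)
  peaks <- sort(unique(peaks))
  # refinement can merge neighbours; re-enforce the refractory period
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) >= refractory * fs)
    while (!all(keep)) {
      drop <- which(!keep)[1L]
      # of the colliding pair keep the taller apex
      if (x[peaks[drop]] > x[peaks[drop - 1L]]) peaks <- peaks[-(drop - 1L)]
      else peaks <- peaks[-drop]
      keep <- c(TRUE, diff(peaks) >= refractory * fs)
    }
  }
  ecg$t0 + (peaks - 1) / fs
}

#' Per-beat windows from R-peak times
#'
#' Beat `i` owns the half-open window from its R peak to the next one; the
#' final R peak opens no window, so windows tile the inter-peak region.
#'
#' @param r_times Strictly increasing R-peak times (>= 2).
#' @return A data.frame with columns `start` and `end` (seconds).
#' @export
beat_windows <- function(r_times) {
  if (length(r_times) < 2L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  if (any(diff(r_times) <= 0)) stop("'r_times' must be strictly increasing")
  n <- length(r_times)
  data.frame(start = r_times[-n], end = r_times[-1L])
}

# samples of a channel inside [start, end)
window_samples <- function(ch, start, end) {
  tt <- channel_times(ch)
  eps <- 0.25 / ch$rate
  ch$samples[tt >= start - eps & tt < end - eps]
}

#' Per-beat pulse pressure from the arterial channel
#'
#' Systolic = window maximum, diastolic = window minimum, pulse pressure =
#' their difference. Windows shorter than 0.2 s are marked invalid rather
#' than raising an error (the beat is dropped downstream).
#'
#' @param abp Arterial `channel_recording` in mmHg.
#' @param start,end Beat window bounds in seconds (half-open).
#' @return List with `systolic`, `diastolic`, `pp`, `map` (window mean) and
#'   `valid`.
#' @export
beat_pulse_pressure <- function(abp, start, end) {
  v <- window_samples(abp, start, end)
  if (length(v) < 0.2 * abp$rate) {
    return(list(systolic = NA_real_, diastolic = NA_real_, pp = NA_real_,
                map = NA_real_, valid = FALSE))
  }
  list(systolic = max(v), diastolic = min(v), pp = max(v) - min(v),
       map = mean(v), valid = TRUE)
}

#' Per-beat photoplethysmographic amplitude
#'
#' Amplitude = max minus min of the PPG within the beat window; invariant
#' to any constant offset, proportional to any gain.
#'
#' @param ppg PPG `channel_recording`.
#' @inheritParams beat_pulse_pressure
#' @return List with `amplitude` and `valid`.
#' @export
beat_pop_amplitude <- function(ppg, start, end) {
  v <- window_samples(ppg, start, end)
  if (length(v) < 0.2 * ppg$rate) {
    return(list(amplitude = NA_real_, valid = FALSE))
  }
  list(amplitude = max(v) - min(v), valid = TRUE)
}

#' Per-beat velocity-time integral from the Doppler envelope
#'
#' Trapezoidal integral of the velocity over the contiguous region around
#' the beat's velocity peak where velocity stays at or above
#' `ejection_threshold_frac` times the peak. Returns 0 when the peak is
#' below the absolute noise floor.
#'
#' @param doppler Doppler `channel_recording` in cm/s.
#' @inheritParams beat_pulse_pressure
#' @param ejection_threshold_frac Fraction of the peak delimiting the
#'   ejection, in `[0, 1)`.
#' @param noise_floor Absolute velocity floor in cm/s.
#' @return List with `vti` (cm) and `valid`.
#' @export
beat_vti <- function(doppler, start, end, ejection_threshold_frac = 0.1,
                     noise_floor = 5) {
  if (ejection_threshold_frac < 0 || ejection_threshold_frac >= 1)
    stop("'ejection_threshold_frac' must lie in [0, 1)")
  v <- window_samples(doppler, start, end)
  if (length(v) < 3L) return(list(vti = NA_real_, valid = FALSE))
  pk <- which.max(v)
  if (v[pk] < noise_floor) return(list(vti = 0, valid = TRUE))
  thr <- ejection_threshold_frac * v[pk]
  lo <- pk; while (lo > 1L && v[lo - 1L] >= thr) lo <- lo - 1L
  hi <- pk; while (hi < length(v) && v[hi + 1L] >= thr) hi <- hi + 1L
  seg <- v[lo:hi]
  dt <- 1 / doppler$rate
  vti <- sum((seg[-1L] + seg[-length(seg)]) / 2) * dt
  list(vti = vti, valid = TRUE)
}

#' Doppler beam geometry
#'
#' @param angle Insonation angle to the aortic flow in degrees
#'   (`0 <= angle < 90`); default 20.
#' @param diameter Assumed aortic diameter in mm; default 20.
#' @return List of class `doppler_geometry`.
#' @export
doppler_geometry <- function(angle = 20, diameter = 20) {
  if (angle < 0 || angle >= 90) stop("'angle' must lie in [0, 90)")
  if (diameter <= 0) stop("'diameter' must be positive")
  structure(list(angle = angle, diameter = diameter),
            class = "doppler_geometry")
}

#' Stroke volume from a beam velocity-time integral
#'
#' `SV [ml] = (VTI / cos(angle)) * pi * (diameter_cm / 2)^2`. The beam
#' measures the velocity component along the probe, underestimating the
#' true aortic velocity by `cos(angle)`, hence the division.
#'
#' @param vti_beam Beam-aligned VTI in cm (>= 0).
#' @param geometry A [doppler_geometry()].
#' @return Stroke volume in ml.
#' @examples
#' stroke_volume(20, doppler_geometry(20, 20))  # ~66.87 ml
#' @export
stroke_volume <- function(vti_beam, geometry = doppler_geometry()) {
  stopifnot(inherits(geometry, "doppler_geometry"))
  if (any(vti_beam < 0, na.rm = TRUE)) stop("'vti_beam' must be non-negative")
  d_cm <- geometry$diameter / 10
  (vti_beam / cos(geometry$angle * pi / 180)) * pi * (d_cm / 2)^2
}

#' Cardiac output from mean stroke volume and heart rate
#'
#' @param sv_mean Mean stroke volume in ml.
#' @param hr Heart rate in beats/min.
#' @return Cardiac output in l/min.
#' @examples
#' cardiac_output(70, 70)  # 4.9
#' @export
cardiac_output <- function(sv_mean, hr) sv_mean * hr / 1000

#' Build the per-beat table for one synchronized segment
#'
#' Detects R peaks on the ECG and computes, for every beat window, pulse
#' pressure (and beat-window MAP), PPG amplitude, Doppler VTI and stroke
#' volume. Channels other than the ECG are optional; their columns are NA
#' when absent.
#'
#' @param segment A `sync_dataset` containing at least an `ecg` channel.
#' @param geometry A [doppler_geometry()].
#' @param ejection_threshold_frac Passed to [beat_vti()].
#' @return A data.frame, one row per beat: `r_time`, `start`, `end`,
#'   `systolic`, `diastolic`, `pulse_pressure`, `map`, `pop_amplitude`,
#'   `vti_beam`, `stroke_volume`, `valid`.
#' @export
beat_table <- function(segment, geometry = doppler_geometry(),
                       ejection_threshold_frac = 0.1) {
  stopifnot(inherits(segment, "sync_dataset"))
  if (is.null(segment$channels$ecg)) stop("segment has no 'ecg' channel")
  r <- detect_r_peaks(segment$channels$ecg)
  win <- beat_windows(r)
  n <- nrow(win)
  out <- data.frame(r_time = win$start, start = win$start, end = win$end,
                    systolic = NA_real_, diastolic = NA_real_,
                    pulse_pressure = NA_real_, map = NA_real_,
                    pop_amplitude = NA_real_, vti_beam = NA_real_,
                    stroke_volume = NA_real_, valid = rep(TRUE, n))
  abp <- segment$channels$abp; ppg <- segment$channels$ppg
  dop <- segment$channels$doppler
  for (i in seq_len(n)) {
    if (!is.null(abp)) {
      bp <- beat_pulse_pressure(abp, win$start[i], win$end[i])
      out$systolic[i] <- bp$systolic; out$diastolic[i] <- bp$diastolic
      out$pulse_pressure[i] <- bp$pp; out$map[i] <- bp$map
      out$valid[i] <- out$valid[i] && bp$valid
    }
    if (!is.null(ppg)) {
      pa <- beat_pop_amplitude(ppg, win$start[i], win$end[i])
      out$pop_amplitude[i] <- pa$amplitude
      out$valid[i] <- out$valid[i] && pa$valid
    }
    if (!is.null(dop)) {
      vt <- beat_vti(dop, win$start[i], win$end[i],
                     ejection_threshold_frac = ejection_threshold_frac)
      out$vti_beam[i] <- vt$vti
      if (vt$valid && !is.na(vt$vti))
        out$stroke_volume[i] <- stroke_volume(vt$vti, geometry)
      out$valid[i] <- out$valid[i] && vt$valid
    }
  }
  out
}
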