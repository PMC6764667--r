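# Beat morphology shared by the arterial and PPG renderers: linear systolic
# upstroke over UPSTROKE_S seconds, then exponential decay back toward the
# beat's starting (diastolic) level with time constant DECAY_TAU_S. The
# simplest shape whose per-beat window max/min are unambiguous: the minimum
# is the first sample of the window, the maximum the top of the upstroke.
UPSTROKE_S <- 0.12
DECAY_TAU_S <- 0.35

# Evaluate seed-scoped code without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a train of R-peak times
#'
#' Beat times are laid down at the nominal inter-beat interval with
#' independent Gaussian timing jitter, then sorted; this is the substrate
#' onto which all waveform renderers place beats.
#'
#' @param heart_rate Mean heart rate in beats/min (> 0).
#' @param duration Train duration in seconds (> 0).
#' @param jitter_sd Standard deviation of per-beat timing jitter in seconds.
#' @param seed Optional integer seed (local to this call).
#' @return Strictly increasing numeric vector of R-peak times in
#'   `[0, duration]`.
#' @examples
#' simulate_beat_train(60, 10)  # 0, 1, ..., 9
#' @export
simulate_beat_train <- function(heart_rate, duration, jitter_sd = 0,
                                seed = NULL) {
  if (!is.finite(heart_rate) || heart_rate <= 0)
    stop("'heart_rate' must be positive")
  if (!is.finite(duration) || duration <= 0)
    stop("'duration' must be positive")
  if (jitter_sd < 0) stop("'jitter_sd' must be non-negative")
  rr <- 60 / heart_rate
  # half-open [0, duration): a 10 s train at 60 beats/min has 10 beats
  base <- rr * (0:max(0L, floor(duration / rr - 1e-9)))
  with_seed(seed, {
    t <- base + if (jitter_sd > 0) stats::rnorm(length(base), 0, jitter_sd) else 0
    t <- sort(t)
    # jitter must not break strict ordering or the duration contract
    t <- pmin(pmax(t, 0), duration)
    keep <- c(TRUE, diff(t) > 0.2 * rr)
    t[keep]
  })
}

# Per-beat half-open windows [t_i, t_{i+1}); the final beat's window is
# closed by the median RR interval, capped at `duration`.
render_windows <- function(beats, duration) {
  n <- length(beats)
  rr <- if (n > 1L) stats::median(diff(beats)) else duration - beats
  ends <- c(beats[-1L], min(beats[n] + rr, duration))
  cbind(start = beats, end = ends)
}

# Unit beat template on relative time within one window: 0 at onset,
# peaks at 1, decays toward 0.
beat_template <- function(t_rel) {
  up <- pmin(t_rel / UPSTROKE_S, 1)
  decay <- exp(-pmax(t_rel - UPSTROKE_S, 0) / DECAY_TAU_S)
  ifelse(t_rel < UPSTROKE_S, up, decay)
}

#' Render a synthetic arterial pressure waveform
#'
#' Per-beat pulse pressure is modulated at the respiratory frequency:
#' `PP_i = mean_pp * (1 + (dpp_target/200) * sin(2*pi*f_r*t_i))` with
#' `f_r = resp_rate/60` and `t_i` the beat's R time, so that the
#' (max-min)/mean definition of dPP applied beat-to-beat recovers
#' `dpp_target` exactly in the limit of dense beat sampling of the
#' respiratory cycle. Each beat's window minimum equals its diastolic
#' pressure and the window mean equals `map_level` (before noise).
#'
#' @param beats R-peak times in seconds (non-empty, increasing).
#' @param map_level Mean arterial pressure in mmHg.
#' @param mean_pp Mean pulse pressure in mmHg.
#' @param dpp_target Target dPP in percent, in `[0, 200)`.
#' @param resp_rate Respiratory rate in breaths/min.
#' @param rate Sampling rate in Hz.
#' @param noise_sd Additive white noise SD in mmHg.
#' @param seed Optional integer seed (local).
#' @param duration Record duration in seconds; defaults to one median RR
#'   beyond the last beat.
#' @return A `channel_recording` labelled `"abp"` in mmHg.
#' @export
render_arterial_waveform <- function(beats, map_level = 90, mean_pp = 40,
                                     dpp_target = 10, resp_rate = 14,
                                     rate = 300, noise_sd = 0, seed = NULL,
                                     duration = NULL) {
  check_render_args(beats, dpp_target, "dpp_target")
  f_r <- resp_rate / 60
  if (is.null(duration))
    duration <- max(beats) + stats::median(diff(c(0, beats)))
  n <- max(2L, ceiling(duration * rate))
  tt <- (seq_len(n) - 1) / rate
  y <- rep(map_level, n)
  win <- render_windows(beats, duration)
  pp <- mean_pp * (1 + (dpp_target / 200) * sin(2 * pi * f_r * beats))
  for (i in seq_along(beats)) {
    idx <- which(tt >= win[i, 1] & tt < win[i, 2])
    if (!length(idx)) next
    u <- beat_template(tt[idx] - win[i, 1])
    dia <- map_level - pp[i] * mean(u)
    y[idx] <- dia + pp[i] * u
  }
  y <- with_seed(seed, y + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  channel_recording(y, rate = rate, label = "abp", units = "mmHg")
}

#' Render a synthetic photoplethysmographic (PPG) waveform
#'
#' The beat-amplitude sequence carries dPOP exactly as the arterial
#' renderer carries dPP; an additive respiratory-frequency baseline wander
#' (which does not change per-beat max-minus-min amplitudes appreciably)
#' tests robustness of the amplitude extraction.
#'
#' @inheritParams render_arterial_waveform
#' @param dpop_target Target dPOP in percent, in `[0, 200)`.
#' @param mean_amplitude Mean beat amplitude in arbitrary units.
#' @param baseline_wander_amp Amplitude of the respiratory baseline wander
#'   (same arbitrary units).
#' @return A `channel_recording` labelled `"ppg"` (a.u.).
#' @export
render_ppg_waveform <- function(beats, dpop_target = 10, resp_rate = 14,
                                rate = 400, baseline_wander_amp = 0.05,
                                noise_sd = 0, seed = NULL,
                                mean_amplitude = 1, duration = NULL) {
  check_render_args(beats, dpop_target, "dpop_target")
  f_r <- resp_rate / 60
  if (is.null(duration))
    duration <- max(beats) + stats::median(diff(c(0, beats)))
  n <- max(2L, ceiling(duration * rate))
  tt <- (seq_len(n) - 1) / rate
  y <- numeric(n)
  win <- render_windows(beats, duration)
  amp <- mean_amplitude * (1 + (dpop_target / 200) * sin(2 * pi * f_r * beats))
  for (i in seq_along(beats)) {
    idx <- which(tt >= win[i, 1] & tt < win[i, 2])
    if (!length(idx)) next
    y[idx] <- amp[i] * beat_template(tt[idx] - win[i, 1])
  }
  y <- y + 2 * mean_amplitude + baseline_wander_amp * sin(2 * pi * f_r * tt)
  y <- with_seed(seed, y + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  channel_recording(y, rate = rate, label = "ppg", units = "a.u.")
}

#' Render a synthetic ECG
#'
#' Sum-of-Gaussians PQRST-like template centred on each beat time; the R
#' apex falls exactly on the requested beat time.
#'
#' @inheritParams render_arterial_waveform
#' @return A `channel_recording` labelled `"ecg"` in mV.
#' @export
render_ecg_waveform <- function(beats, rate = 300, noise_sd = 0, seed = NULL,
                                duration = NULL) {
  if (length(beats) == 0L) stop("'beats' must be non-empty")
  if (is.null(duration))
    duration <- max(beats) + stats::median(diff(c(0, beats)))
  n <- max(2L, ceiling(duration * rate))
  tt <- (seq_len(n) - 1) / rate
  y <- numeric(n)
  g <- function(center, amp, width) {
    for (tb in beats) y <<- y + amp * exp(-((tt - tb - center)^2) / (2 * width^2))
    invisible(NULL)
  }
  g(0, 1, 0.008)        # R
  g(-0.035, -0.15, 0.012)  # Q
  g(0.035, -0.2, 0.012)    # S
  g(0.28, 0.25, 0.06)      # T
  y <- with_seed(seed, y + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  channel_recording(y, rate = rate, label = "ecg", units = "mV")
}

#' Render a synthetic central venous pressure waveform
#'
#' CVP is a respiratory sinusoid of peak-to-trough amplitude `dcvp_target`
#' around `mean_cvp`, with a small cardiac bump at each beat. `mode`
#' controls how airway pressure shifts the waveform: PEP-like raises only
#' the expiratory (positive) half by `peak_offset` (so cycle maxima rise
#' while minima stay put); CPAP-like shifts the whole baseline by
#' `baseline_offset` (maxima and minima rise together, leaving the
#' peak-to-trough swing unchanged).
#'
#' @inheritParams render_arterial_waveform
#' @param mean_cvp Mean CVP in mmHg.
#' @param dcvp_target Peak-to-trough respiratory swing in mmHg (>= 0).
#' @param cardiac_amp Amplitude of the cardiac oscillation in mmHg; should
#'   be below `dcvp_target / 2` for the swing to dominate.
#' @param mode `"neutral"`, `"PEP"` or `"CPAP"`.
#' @param peak_offset Expiratory peak elevation in mmHg (PEP mode).
#' @param baseline_offset Whole-waveform shift in mmHg (CPAP mode).
#' @return A `channel_recording` labelled `"cvp"` in mmHg.
#' @export
render_cvp_waveform <- function(mean_cvp = 6, dcvp_target = 3, resp_rate = 14,
                                cardiac_amp = 0.5, beats = numeric(0),
                                mode = c("neutral", "PEP", "CPAP"),
                                rate = 400, noise_sd = 0, seed = NULL,
                                peak_offset = 0, baseline_offset = 0,
                                duration = NULL) {
  mode <- match.arg(mode)
  if (dcvp_target < 0) stop("'dcvp_target' must be non-negative")
  if (is.null(duration)) {
    if (length(beats)) duration <- max(beats) + 1
    else duration <- 3 * 60 / resp_rate
  }
  f_r <- resp_rate / 60
  n <- max(2L, ceiling(duration * rate))
  tt <- (seq_len(n) - 1) / rate
  resp <- (dcvp_target / 2) * sin(2 * pi * f_r * tt)
  y <- mean_cvp + resp
  if (mode == "PEP" && peak_offset != 0)
    y <- y + peak_offset * pmax(0, sin(2 * pi * f_r * tt))
  if (mode == "CPAP") y <- y + baseline_offset
  if (cardiac_amp > 0 && length(beats)) {
    bump_dur <- 0.35
    for (tb in beats) {
      idx <- which(tt >= tb & tt < tb + bump_dur)
      if (length(idx))
        y[idx] <- y[idx] + cardiac_amp * sin(pi * (tt[idx] - tb) / bump_dur)
    }
  }
  y <- with_seed(seed, y + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  channel_recording(y, rate = rate, label = "cvp", units = "mmHg")
}

#' Render a synthetic aortic Doppler velocity envelope
#'
#' Each beat produces a half-sine ejection pulse whose beam-aligned
#' velocity-time integral equals `sv * cos(angle) / area`, i.e. the exact
#' inverse of the stroke-volume formula, so that downstream
#' [stroke_volume()] with the same geometry recovers `sv_targets`.
#'
#' @inheritParams render_arterial_waveform
#' @param sv_targets Per-beat stroke volumes in ml (length = number of
#'   beats).
#' @param angle Insonation angle in degrees.
#' @param diameter Aortic diameter in mm.
#' @param ejection_duration Ejection time in seconds.
#' @return A `channel_recording` labelled `"doppler"` in cm/s.
#' @export
render_doppler_velocity <- function(beats, sv_targets, angle = 20,
                                    diameter = 20, rate = 300, noise_sd = 0,
                                    seed = NULL, ejection_duration = 0.3,
                                    duration = NULL) {
  if (length(beats) == 0L) stop("'beats' must be non-empty")
  if (length(sv_targets) != length(beats))
    stop("'sv_targets' must have one entry per beat")
  area <- pi * (diameter / 20)^2  # cm^2
  vti_beam <- sv_targets * cos(angle * pi / 180) / area  # cm
  peak_v <- vti_beam / ((2 / pi) * ejection_duration)    # cm/s
  if (is.null(duration))
    duration <- max(beats) + stats::median(diff(c(0, beats)))
  n <- max(2L, ceiling(duration * rate))
  tt <- (seq_len(n) - 1) / rate
  y <- numeric(n)
  for (i in seq_along(beats)) {
    idx <- which(tt >= beats[i] & tt < beats[i] + ejection_duration)
    if (length(idx))
      y[idx] <- peak_v[i] * sin(pi * (tt[idx] - beats[i]) / ejection_duration)
  }
  y <- with_seed(seed, y + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0)
  channel_recording(y, rate = rate, label = "doppler", units = "cm/s")
}

check_render_args <- function(beats, target, what) {
  if (length(beats) == 0L) stop("'beats' must be non-empty")
  if (any(diff(beats) <= 0)) stop("'beats' must be strictly increasing")
  if (!is.finite(target) || target < 0 || target >= 200)
    stop(sprintf("'%s' must lie in [0, 200)", what))
  invisible(NULL)
}
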