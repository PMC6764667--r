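#' Respiratory variation in pulse pressure (dPP)
#'
#' For the member beats of one respiratory cycle,
#' `dPP = (PP_max - PP_min) / ((PP_max + PP_min) / 2) * 100` percent, where
#' `PP_max` and `PP_min` are the largest and smallest per-beat pulse
#' pressures within the cycle. At least 3 valid beats are required (the
#' maximum and minimum must be distinct beats); with fewer the cycle is
#' rejected.
#'
#' @param pp Numeric vector of per-beat pulse pressures (mmHg) within one
#'   respiratory cycle; NAs are dropped.
#' @return List with `max`, `min`, `value` (percent) — or `NULL` if fewer
#'   than 3 valid beats remain.
#' @examples
#' dpp(c(40, 50, 60))$value  # 40
#' @export
dpp <- function(pp) {
  pp <- pp[is.finite(pp)]
  if (length(pp) < 3L) return(NULL)
  amplitude_variation(pp)
}

#' Respiratory variation in PPG waveform amplitude (dPOP)
#'
#' Identical statistic to [dpp()] computed on per-beat photoplethysmographic
#' amplitudes; invariant to the oximeter's gain.
#'
#' @param pop Numeric vector of per-beat PPG amplitudes (a.u.) within one
#'   respiratory cycle; NAs are dropped.
#' @return List with `max`, `min`, `value` (percent) — or `NULL` if fewer
#'   than 3 valid beats remain.
#' @export
dpop <- function(pop) {
  pop <- pop[is.finite(pop)]
  if (length(pop) < 3L) return(NULL)
  amplitude_variation(pop)
}

amplitude_variation <- function(v) {
  vmax <- max(v); vmin <- min(v)
  mid <- (vmax + vmin) / 2
  val <- if (mid > 0) (vmax - vmin) / mid * 100 else if (vmax == vmin) 0 else NA_real_
  list(max = vmax, min = vmin, value = val)
}

#' Respiratory variation in central venous pressure (dCVP)
#'
#' Peak minus trough of the 40 Hz downsampled CVP waveform within one
#' respiratory cycle. The channel must already be at 40 Hz (downsample with
#' [resample_channel()] once per segment, then evaluate per cycle), per the
#' stated order of operations.
#'
#' @param cvp_40hz A `channel_recording` at 40 Hz.
#' @param start,end Cycle interval in seconds (half-open).
#' @return List with `peak`, `trough`, `value` (mmHg) — or `NULL` if the
#'   interval holds fewer than 10 samples.
#' @export
dcvp <- function(cvp_40hz, start, end) {
  stopifnot(inherits(cvp_40hz, "channel_recording"))
  if (abs(cvp_40hz$rate - 40) > 1e-6)
    stop("'cvp_40hz' must be sampled at 40 Hz (use resample_channel first)")
  v <- window_samples(cvp_40hz, start, end)
  if (length(v) < 10L) return(NULL)
  list(peak = max(v), trough = min(v), value = max(v) - min(v))
}

#' Quality-control thresholds for respiratory cycles
#'
#' Automated stand-in for visual inspection of cycles: each cycle is
#' checked against physiologic plausibility bounds and every rejection
#' carries a reason.
#'
#' @param duration_range Acceptable cycle duration in seconds.
#' @param min_beats Minimum valid member beats.
#' @param max_variation Maximum plausible dPP/dPOP in percent.
#' @param max_pp_jump_frac Maximum adjacent-beat pulse-pressure jump, as a
#'   fraction of the sequence median PP.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(duration_range = c(1.5, 12), min_beats = 3L,
                          max_variation = 150, max_pp_jump_frac = 0.5) {
  structure(list(duration_range = duration_range, min_beats = min_beats,
                 max_variation = max_variation,
                 max_pp_jump_frac = max_pp_jump_frac),
            class = "qc_thresholds")
}

#' Quality-control one respiratory cycle
#'
#' @param duration Cycle duration in seconds.
#' @param pp Member-beat pulse pressures (may contain NA).
#' @param dpp_value,dpop_value Computed variations in percent (NA allowed).
#' @param pp_seq_median Median pulse pressure of the whole sequence, for
#'   the adjacent-beat jump check.
#' @param thresholds A [qc_thresholds()].
#' @return List with `accepted` (flag) and `reasons` (character vector,
#'   empty when accepted).
#' @export
qc_cycle <- function(duration, pp, dpp_value = NA, dpop_value = NA,
                     pp_seq_median = stats::median(pp, na.rm = TRUE),
                     thresholds = qc_thresholds()) {
  reasons <- character(0)
  if (duration < thresholds$duration_range[1] ||
      duration > thresholds$duration_range[2]) reasons <- c(reasons, "duration")
  n_valid <- sum(is.finite(pp))
  if (n_valid < thresholds$min_beats) reasons <- c(reasons, "too-few-beats")
  if (any(is.finite(pp) & pp <= 0)) reasons <- c(reasons, "nonpositive-PP")
  if (isTRUE(is.finite(dpp_value) && dpp_value > thresholds$max_variation) ||
      isTRUE(is.finite(dpop_value) && dpop_value > thresholds$max_variation))
    reasons <- c(reasons, "excessive-variation")
  ppf <- pp[is.finite(pp)]
  if (length(ppf) > 1L && is.finite(pp_seq_median) && pp_seq_median > 0 &&
      any(abs(diff(ppf)) > thresholds$max_pp_jump_frac * pp_seq_median))
    reasons <- c(reasons, "pp-jump")
  list(accepted = length(reasons) == 0L, reasons = reasons)
}

#' Trimmed mean, trimming a fixed count per tail
#'
#' Drops `k = floor(trim_frac * n)` smallest and `k` largest values and
#' averages the remainder; with the default 5 percent trim and n < 20 no
#' value is dropped (floor rule, stated because rounding conventions
#' differ).
#'
#' @param values Non-empty numeric vector (NAs dropped).
#' @param trim_frac Fraction per tail, in `[0, 0.5)`.
#' @return The trimmed mean.
#' @examples
#' trimmed_mean(1:20)  # drops 1 and 20 -> 10.5
#' @export
trimmed_mean <- function(values, trim_frac = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("'values' must contain at least one finite value")
  if (trim_frac < 0 || trim_frac >= 0.5) stop("'trim_frac' must lie in [0, 0.5)")
  k <- floor(trim_frac * length(values))
  v <- sort(values)
  if (k > 0L) v <- v[(k + 1L):(length(v) - k)]
  mean(v)
}

#' Compute per-cycle metrics for one annotated segment
#'
#' Runs the full per-segment chain: beat table, respiratory surrogate,
#' cycle segmentation, beat-to-cycle assignment, per-cycle dPP/dPOP, dCVP
#' on the 40 Hz downsampled CVP, and quality control.
#'
#' @param segment A `sync_dataset` (from [extract_segment()] or a simulated
#'   study) with at least `ecg` and `abp` channels.
#' @param geometry A [doppler_geometry()].
#' @param thresholds A [qc_thresholds()].
#' @param cvp_target_rate Downsampling target for dCVP in Hz.
#' @param ejection_threshold_frac Passed to [beat_vti()].
#' @return List with `beats` (per-beat table including `cycle`) and
#'   `cycles`: one row per respiratory cycle with columns `start`, `end`,
#'   `duration`, `resp_rate`, `n_beats`, `pp_max`, `pp_min`, `dpp`,
#'   `pop_max`, `pop_min`, `dpop`, `cvp_peak`, `cvp_trough`, `dcvp`,
#'   `accepted`, `reject_reason`, plus any segment metadata columns.
#' @export
compute_cycle_metrics <- function(segment, geometry = doppler_geometry(),
                                  thresholds = qc_thresholds(),
                                  cvp_target_rate = 40,
                                  ejection_threshold_frac = 0.1) {
  beats <- beat_table(segment, geometry = geometry,
                      ejection_threshold_frac = ejection_threshold_frac)
  resp <- derive_respiratory_signal(segment, beats = beats)
  cycles <- detect_respiratory_cycles(resp)
  beats <- assign_beats_to_cycles(beats, cycles)
  cvp40 <- if (!is.null(segment$channels$cvp))
    resample_channel(segment$channels$cvp, cvp_target_rate) else NULL
  pp_seq_median <- stats::median(beats$pulse_pressure, na.rm = TRUE)
  n_cyc <- nrow(cycles)
  res <- data.frame(
    start = cycles$start, end = cycles$end, duration = cycles$duration,
    resp_rate = cycles$resp_rate, n_beats = 0L,
    pp_max = NA_real_, pp_min = NA_real_, dpp = NA_real_,
    pop_max = NA_real_, pop_min = NA_real_, dpop = NA_real_,
    cvp_peak = NA_real_, cvp_trough = NA_real_, dcvp = NA_real_,
    accepted = FALSE, reject_reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(n_cyc)) {
    member <- beats[!is.na(beats$cycle) & beats$cycle == i & beats$valid, ]
    res$n_beats[i] <- nrow(member)
    dp <- dpp(member$pulse_pressure)
    if (!is.null(dp)) {
      res$pp_max[i] <- dp$max; res$pp_min[i] <- dp$min; res$dpp[i] <- dp$value
    }
    po <- dpop(member$pop_amplitude)
    if (!is.null(po)) {
      res$pop_max[i] <- po$max; res$pop_min[i] <- po$min; res$dpop[i] <- po$value
    }
    if (!is.null(cvp40)) {
      dc <- dcvp(cvp40, cycles$start[i], cycles$end[i])
      if (!is.null(dc)) {
        res$cvp_peak[i] <- dc$peak; res$cvp_trough[i] <- dc$trough
        res$dcvp[i] <- dc$value
      }
    }
    qc <- qc_cycle(cycles$duration[i], member$pulse_pressure,
                   dpp_value = res$dpp[i], dpop_value = res$dpop[i],
                   pp_seq_median = pp_seq_median, thresholds = thresholds)
    res$accepted[i] <- qc$accepted
    res$reject_reason[i] <- paste(qc$reasons, collapse = ";")
  }
  if (!is.null(segment$meta)) {
    for (nm in names(segment$meta)) res[[nm]] <- segment$meta[[nm]]
  }
  list(beats = beats, cycles = res)
}

#' Summarize one sequence (subject x LBNP x intervention x resistance)
#'
#' Static hemodynamics (stroke volume, heart rate from R-R intervals, MAP,
#' mean CVP) are summarized by the 5 percent trimmed mean over the
#' sequence; the dynamic variables by the median over accepted respiratory
#' cycles.
#'
#' @param cycles Cycle table from [compute_cycle_metrics()].
#' @param beats Beat table from [compute_cycle_metrics()].
#' @param segment The `sync_dataset` the tables came from (for mean CVP).
#' @param trim_frac Trim fraction per tail.
#' @return One-row data.frame: metadata, `sv`, `hr`, `map`, `cvp`,
#'   `dpp_med`, `dpop_med`, `dcvp_med`, `n_cycles_accepted`, `trim_frac`.
#' @export
summarize_level <- function(cycles, beats, segment = NULL, trim_frac = 0.05) {
  acc <- cycles[cycles$accepted, , drop = FALSE]
  rr <- diff(beats$r_time)
  hr <- if (length(rr)) trimmed_mean(60 / rr, trim_frac) else NA_real_
  sv <- if (any(is.finite(beats$stroke_volume)))
    trimmed_mean(beats$stroke_volume, trim_frac) else NA_real_
  map <- if (any(is.finite(beats$map)))
    trimmed_mean(beats$map, trim_frac) else NA_real_
  cvp <- if (!is.null(segment) && !is.null(segment$channels$cvp))
    trimmed_mean(segment$channels$cvp$samples, trim_frac) else NA_real_
  med_or_na <- function(v) if (any(is.finite(v))) stats::median(v, na.rm = TRUE) else NA_real_
  out <- data.frame(sv = sv, hr = hr, map = map, cvp = cvp,
                    dpp_med = med_or_na(acc$dpp),
                    dpop_med = med_or_na(acc$dpop),
                    dcvp_med = med_or_na(acc$dcvp),
                    n_cycles_accepted = nrow(acc), trim_frac = trim_frac)
  meta_cols <- intersect(c("subject", "lbnp", "intervention", "resistance"),
                         names(cycles))
  if (length(meta_cols) && nrow(cycles))
    out <- cbind(cycles[1L, meta_cols, drop = FALSE], out, row.names = NULL)
  out
}
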