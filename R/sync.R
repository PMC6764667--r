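#' Synchronized multichannel dataset
#'
#' Crops a set of channels sharing one clock to their common time overlap
#' (or a requested sub-span). No resampling is performed.
#'
#' @param channels A list of [channel_recording()] objects; names default to
#'   the channel labels. Labels must be unique.
#' @param span Optional `c(start, end)` in seconds to crop to; must lie
#'   within the common overlap.
#' @param meta Optional named list of metadata (subject, lbnp, ...).
#' @return An object of class `sync_dataset`: list with elements
#'   `channels` (named list) and `span`.
#' @export
synchronize <- function(channels, span = NULL, meta = NULL) {
  stopifnot(is.list(channels), length(channels) > 0L)
  ok <- vapply(channels, inherits, TRUE, what = "channel_recording")
  if (!all(ok)) stop("all elements of 'channels' must be channel_recording objects")
  labs <- vapply(channels, `[[`, "", "label")
  if (is.null(names(channels))) names(channels) <- labs
  if (anyDuplicated(names(channels))) stop("channel labels must be unique")
  t_start <- max(vapply(channels, `[[`, 0, "t0"))
  t_end <- min(vapply(channels, channel_end, 0))
  if (t_end <= t_start) stop("channels have no common time overlap")
  if (!is.null(span)) {
    if (span[1] < t_start - 1e-9 || span[2] > t_end + 1e-9)
      stop(sprintf("requested span [%g, %g] outside common overlap [%g, %g]",
                   span[1], span[2], t_start, t_end))
    t_start <- span[1]; t_end <- span[2]
  }
  channels <- lapply(channels, crop_channel, start = t_start, end = t_end,
                     closed_end = TRUE)
  structure(list(channels = channels, span = c(t_start, t_end), meta = meta),
            class = "sync_dataset")
}

#' @export
print.sync_dataset <- function(x, ...) {
  cat(sprintf("<sync_dataset> %d channels (%s), span [%g, %g] s\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$span[1], x$span[2]))
  if (!is.null(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Resample a channel to a new rate
#'
#' For downsampling, a zero-phase Butterworth low-pass (order 4, cutoff
#' 0.45 times the target rate) is applied before linear interpolation onto
#' the new sample grid, so that peaks and troughs are not phase-shifted
#' (this matters for CVP peak/trough extraction). The DC level is preserved
#' exactly for constant signals, and the operation is linear in the input.
#'
#' @param x A `channel_recording`.
#' @param target_rate New rate in Hz (> 0).
#' @return A `channel_recording` at `target_rate` spanning the same interval.
#' @export
resample_channel <- function(x, target_rate) {
  stopifnot(inherits(x, "channel_recording"))
  if (!is.finite(target_rate) || target_rate <= 0)
    stop("'target_rate' must be positive")
  if (isTRUE(all.equal(target_rate, x$rate))) return(x)
  y <- x$samples
  if (target_rate < x$rate)
    y <- lowpass(y, x$rate, cutoff = 0.45 * target_rate, order = 4L)
  tt <- channel_times(x)
  dur <- (length(y) - 1) / x$rate
  n_out <- floor(dur * target_rate) + 1L
  t_out <- x$t0 + (seq_len(n_out) - 1) / target_rate
  out <- stats::approx(tt, y, xout = t_out, rule = 2)$y
  channel_recording(out, rate = target_rate, label = x$label, units = x$units,
                    t0 = x$t0)
}

#' Extract one annotated segment from a synchronized dataset
#'
#' Crops every channel to the half-open interval `[start, end)` of one
#' annotation record and attaches the record's condition metadata.
#'
#' @param dataset A `sync_dataset`.
#' @param record One-row `data.frame` (or list) with at least `start` and
#'   `end`, and optionally `subject`, `lbnp`, `intervention`, `resistance`.
#' @return A `sync_dataset` restricted to the interval, with `meta` set.
#' @export
extract_segment <- function(dataset, record) {
  stopifnot(inherits(dataset, "sync_dataset"))
  s <- as.numeric(record[["start"]]); e <- as.numeric(record[["end"]])
  if (!(e > s)) stop("annotation interval must have end > start")
  # the dataset span ends at its last sample; a half-open interval may
  # legitimately end up to a couple of sample periods beyond it (each
  # synchronize/crop cycle can trim one boundary sample per channel)
  slack <- 2 * max(vapply(dataset$channels, function(ch) 1 / ch$rate, 0))
  if (s < dataset$span[1] - 1e-9 || e > dataset$span[2] + slack + 1e-9)
    stop(sprintf("interval [%g, %g) outside dataset span [%g, %g]",
                 s, e, dataset$span[1], dataset$span[2]))
  chans <- lapply(dataset$channels, crop_channel, start = s, end = e,
                  closed_end = FALSE)
  meta <- record[intersect(c("subject", "lbnp", "intervention", "resistance"),
                           names(record))]
  structure(list(channels = chans, span = c(s, e), meta = as.list(meta)),
            class = "sync_dataset")
}
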