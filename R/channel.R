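#' Uniformly sampled waveform channel
#'
#' Container for one uniformly sampled physiological signal. Sample `k`
#' (1-based) sits at time `t0 + (k - 1) / rate` seconds.
#'
#' @param samples Numeric vector of samples (non-empty, finite).
#' @param rate Sampling rate in Hz (> 0).
#' @param label Channel name, e.g. `"ecg"`, `"abp"`, `"ppg"`, `"cvp"`,
#'   `"doppler"`.
#' @param units Unit string, e.g. `"mmHg"`, `"mV"`, `"a.u."`, `"cm/s"`.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `channel_recording`.
#' @examples
#' ch <- channel_recording(sin(2 * pi * 0.25 * seq(0, 10, by = 1 / 40)),
#'                         rate = 40, label = "cvp", units = "mmHg")
#' ch
#' @export
channel_recording <- function(samples, rate, label = "signal",
                              units = "a.u.", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number (Hz)")
  if (!is.finite(t0)) stop("'t0' must be finite")
  structure(
    list(label = as.character(label)[1L], samples = samples,
         rate = as.numeric(rate), t0 = as.numeric(t0),
         units = as.character(units)[1L]),
    class = "channel_recording"
  )
}

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf("<channel_recording> %s: %d samples @ %g Hz, t = [%g, %g] s, units = %s\n",
              x$label, length(x$samples), x$rate, x$t0, channel_end(x), x$units))
  invisible(x)
}

#' @export
length.channel_recording <- function(x) length(x$samples)

#' Sample times of a channel
#' @param x A `channel_recording`.
#' @return Numeric vector of sample times in seconds.
#' @export
channel_times <- function(x) {
  stopifnot(inherits(x, "channel_recording"))
  x$t0 + (seq_along(x$samples) - 1) / x$rate
}

# time of the last sample
channel_end <- function(x) x$t0 + (length(x$samples) - 1) / x$rate

#' Crop a channel to a time interval
#'
#' Intervals are half-open `[start, end)` by default, so adjacent segments
#' tile a recording without sharing samples.
#'
#' @param x A `channel_recording`.
#' @param start,end Interval bounds in seconds.
#' @param closed_end Include a sample falling exactly on `end`.
#' @return A `channel_recording` covering the interval.
#' @export
crop_channel <- function(x, start, end, closed_end = FALSE) {
  stopifnot(inherits(x, "channel_recording"))
  if (!(end > start)) stop("'end' must be greater than 'start'")
  tt <- channel_times(x)
  eps <- 0.25 / x$rate  # guard against floating-point grid drift
  keep <- tt >= start - eps & (if (closed_end) tt <= end + eps else tt < end - eps)
  if (!any(keep)) stop(sprintf("no samples of channel '%s' in [%g, %g)", x$label, start, end))
  idx <- range(which(keep))
  channel_recording(x$samples[idx[1L]:idx[2L]], rate = x$rate, label = x$label,
                    units = x$units, t0 = tt[idx[1L]])
}

#' Write a channel to the canonical delimited-text format
#'
#' The canonical dialect is UTF-8 text: four header lines
#' `# label:`, `# rate:`, `# units:`, `# t0:` followed by one sample per
#' line, printed with 17 significant digits so that a write/read cycle is
#' bit-exact for doubles.
#'
#' @param x A `channel_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_channel_text()]
#' @export
write_channel_text <- function(x, path) {
  stopifnot(inherits(x, "channel_recording"))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  header <- c(
    sprintf("# label: %s", x$label),
    sprintf("# rate: %.17g", x$rate),
    sprintf("# units: %s", x$units),
    sprintf("# t0: %.17g", x$t0)
  )
  writeLines(c(header, sprintf("%.17g", x$samples)), con, sep = "\n")
  invisible(path)
}

#' Read a channel from delimited text
#'
#' Two dialects are supported. `"canonical"` is the format written by
#' [write_channel_text()]. `"two_column"` is a headerless file with a time
#' column (seconds) and a value column, separated by whitespace or commas;
#' the rate is inferred as the reciprocal of the median time step and the
#' time column must be uniform (strictly increasing with no gaps).
#'
#' @param path Input file path.
#' @param dialect `"canonical"` or `"two_column"`.
#' @param label,units Metadata for the `"two_column"` dialect (which carries
#'   none); ignored for `"canonical"`.
#' @return A `channel_recording`.
#' @export
read_channel_text <- function(path, dialect = c("canonical", "two_column"),
                              label = "signal", units = "a.u.") {
  dialect <- match.arg(dialect)
  lines <- readLines(path, encoding = "UTF-8")
  if (dialect == "canonical") {
    hdr_idx <- grep("^#", lines)
    if (length(hdr_idx) && any(diff(hdr_idx) != 1L))
      stop("header lines ('#') must precede all samples in ", path)
    hdr <- lines[hdr_idx]
    get_field <- function(name) {
      m <- grep(sprintf("^#\\s*%s:", name), hdr, value = TRUE)
      if (length(m) == 0L)
        stop(sprintf("missing header field '%s' in %s", name, path))
      trimws(sub(sprintf("^#\\s*%s:", name), "", m[1L]))
    }
    lab <- get_field("label"); un <- get_field("units")
    rate <- suppressWarnings(as.numeric(get_field("rate")))
    t0 <- suppressWarnings(as.numeric(get_field("t0")))
    if (!isTRUE(is.finite(rate))) stop("non-numeric 'rate' header in ", path)
    if (!isTRUE(is.finite(t0))) stop("non-numeric 't0' header in ", path)
    body_idx <- setdiff(seq_along(lines), hdr_idx)
    body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
    vals <- suppressWarnings(as.numeric(lines[body_idx]))
    if (anyNA(vals)) {
      bad <- body_idx[which(is.na(vals))[1L]]
      stop(sprintf("non-numeric sample at line %d of %s", bad, path))
    }
    if (length(vals) == 0L) stop("no samples in ", path)
    channel_recording(vals, rate = rate, label = lab, units = un, t0 = t0)
  } else {
    keep <- which(nzchar(trimws(lines)))
    parts <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
    ncol_ok <- vapply(parts, length, 1L) >= 2L
    if (!all(ncol_ok))
      stop(sprintf("expected two columns at line %d of %s", keep[which(!ncol_ok)[1L]], path))
    tcol <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    vcol <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (anyNA(tcol) || anyNA(vcol)) {
      bad <- keep[which(is.na(tcol) | is.na(vcol))[1L]]
      stop(sprintf("non-numeric value at line %d of %s", bad, path))
    }
    if (length(tcol) < 2L) stop("need at least two samples to infer a rate: ", path)
    dt <- diff(tcol)
    if (any(dt <= 0))
      stop(sprintf("non-monotone time column at line %d of %s",
                   keep[which(dt <= 0)[1L] + 1L], path))
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop(sprintf("gap or irregular time step at line %d of %s",
                   keep[which(abs(dt - med) > 0.01 * med)[1L] + 1L], path))
    channel_recording(vcol, rate = 1 / med, label = label, units = units,
                      t0 = tcol[1L])
  }
}

#' Protocol annotation table
#'
#' Builds and validates the interval-to-condition mapping for a study:
#' which subject, lower body negative pressure (LBNP) level, intervention
#' (PEP or CPAP) and airway resistance level each time interval belongs to.
#'
#' @param subject Character or integer vector of subject ids.
#' @param start,end Interval bounds in seconds (half-open `[start, end)`).
#' @param lbnp LBNP level in mmHg; one of 0, 20, 40, 60, 80.
#' @param intervention `"PEP"` or `"CPAP"`.
#' @param resistance Airway pressure level in cmH2O; one of 0, 5, 10.
#' @return A `data.frame` of class `protocol_annotation`.
#' @export
protocol_annotation <- function(subject, start, end, lbnp, intervention,
                                resistance) {
  df <- data.frame(subject = as.character(subject), start = as.numeric(start),
                   end = as.numeric(end), lbnp = as.numeric(lbnp),
                   intervention = as.character(intervention),
                   resistance = as.numeric(resistance),
                   stringsAsFactors = FALSE)
  validate_annotation(df)
  class(df) <- c("protocol_annotation", "data.frame")
  df
}

validate_annotation <- function(df) {
  if (any(df$end <= df$start)) stop("annotation intervals must have end > start")
  if (!all(df$lbnp %in% c(0, 20, 40, 60, 80)))
    stop("lbnp must be one of 0, 20, 40, 60, 80 mmHg")
  if (!all(df$intervention %in% c("PEP", "CPAP")))
    stop("intervention must be 'PEP' or 'CPAP'")
  if (!all(df$resistance %in% c(0, 5, 10)))
    stop("resistance must be one of 0, 5, 10 cmH2O")
  for (s in unique(df$subject)) {
    d <- df[df$subject == s, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)] - 1e-9))
      stop("overlapping annotation intervals for subject ", s)
  }
  invisible(df)
}

#' Write / read a protocol annotation as JSON
#'
#' @param x A `protocol_annotation`.
#' @param path File path.
#' @return `write_protocol_json()` returns `path` invisibly;
#'   `read_protocol_json()` returns a `protocol_annotation`.
#' @export
write_protocol_json <- function(x, path) {
  stopifnot(inherits(x, "protocol_annotation"))
  jsonlite::write_json(as.data.frame(unclass(x), stringsAsFactors = FALSE),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  protocol_annotation(df$subject, df$start, df$end, df$lbnp,
                      df$intervention, df$resistance)
}
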