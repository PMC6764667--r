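# Zero-phase filtering with reflection padding.
#
# signal::filtfilt pads only by a couple of filter lengths, which leaves
# visible transients at the edges of short physiological segments; peaks and
# troughs near segment edges feed straight into dCVP and respiratory-cycle
# boundaries, so edges matter here. We mirror the signal about both endpoints
# (even reflection), forward-backward filter, and keep the middle.
zerophase_filter <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 3L * max(length(filt$b), length(filt$a), 50L))
  pad <- max(0L, min(as.integer(pad), n - 1L))
  if (pad > 0L) {
    xe <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  } else {
    xe <- x
  }
  y <- signal::filtfilt(filt, xe)
  if (pad > 0L) y <- y[(pad + 1L):(pad + n)]
  y
}

# Zero-phase Butterworth low-pass. cutoff in Hz, rate in Hz.
lowpass <- function(x, rate, cutoff, order = 4L, pad = NULL) {
  w <- cutoff / (rate / 2)
  if (w >= 1) return(x)
  mu <- mean(x)  # filter the fluctuation only: exact DC preservation
  bf <- signal::butter(order, w, type = "low")
  mu + zerophase_filter(bf, x - mu, pad = pad)
}

# Zero-phase Butterworth band-pass, band = c(low, high) in Hz.
bandpass <- function(x, rate, band, order = 2L, pad = NULL) {
  w <- band / (rate / 2)
  w[2] <- min(w[2], 0.99)
  stopifnot(w[1] > 0, w[1] < w[2])
  bf <- signal::butter(order, w, type = "pass")
  zerophase_filter(bf, x - mean(x), pad = pad)
}

# Local maxima (strict rises, plateaus resolved to their first sample),
# with an optional minimum separation in samples; taller peak wins ties.
local_maxima <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  rise <- d > 0; fall <- d < 0
  cand <- which(rise[-(n - 1L)] & fall[-1L]) + 1L
  if (length(cand) == 0L || min_sep <= 1L) return(cand)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

local_minima <- function(x, min_sep = 1L) local_maxima(-x, min_sep = min_sep)
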