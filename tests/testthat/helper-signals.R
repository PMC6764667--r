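# Shared fixtures, built in code.

# a pure sinusoid channel
sin_channel <- function(freq, duration, rate, amp = 1, mean = 0,
                        label = "sig", units = "a.u.") {
  t <- seq(0, duration, by = 1 / rate)
  channel_recording(mean + amp * sin(2 * pi * freq * t), rate = rate,
                    label = label, units = units)
}

# noiseless small-study configuration used by end-to-end tests:
# slow breathing (6 breaths/min at HR ~70 gives > 10 beats per cycle)
noiseless_config <- function(...) {
  defaults <- list(resp_rate = c(mean = 6, sd = 0),
                   noise_sd = c(ecg = 0, abp = 0, ppg = 0, cvp = 0,
                                doppler = 0))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# balanced noiseless outcome table generated directly from the linear
# mixed-model structure (no waveforms); subject intercepts passed in
lmm_table <- function(b0 = log(8), slope = 0.1,
                      inter = c("0" = 0, "5" = 0.05, "10" = 0.08),
                      subj_int = rep(0, 4), steps = 0:4, eps_sd = 0,
                      seed = 1) {
  set.seed(seed)
  g <- expand.grid(subject = seq_along(subj_int), step = steps,
                   resistance = as.numeric(names(inter)))
  eta <- b0 + (slope + inter[as.character(g$resistance)]) * g$step +
    subj_int[g$subject] + if (eps_sd > 0) rnorm(nrow(g), 0, eps_sd) else 0
  data.frame(subject = sprintf("S%02d", g$subject), lbnp = g$step * 20,
             resistance = g$resistance, intervention = "PEP",
             dpp = exp(eta), stringsAsFactors = FALSE)
}
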