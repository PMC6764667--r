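#' Simulate a study and write it to disk
#'
#' Thin pipeline stage around [simulate_study()] + [write_study()]: renders
#' the multichannel dataset, the protocol annotation, the truth table and a
#' manifest (config hash + per-file fingerprints) under `out_dir`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config, out_dir, quiet = FALSE) {
  study <- simulate_study(config)
  manifest <- write_study(study, out_dir)
  if (!quiet)
    message(sprintf("simulate: %d subjects, %d sequences -> %s (config %s)",
                    length(study$subjects), nrow(study$truth), out_dir,
                    manifest$config_hash))
  invisible(manifest)
}

#' Analyze an annotated multichannel dataset into cycle metrics
#'
#' For every annotated sequence: extract the segment, detect beats and
#' respiratory cycles, compute per-cycle dPP/dPOP/dCVP, apply quality
#' control, and log accepted/rejected counts. A sequence whose channels
#' cannot be processed is skipped with a logged error; the run continues.
#'
#' @param study A `pulsevar_study` (in memory) or a directory written by
#'   [run_simulate()] / [write_study()].
#' @param out_csv Optional path for the cycle-metrics CSV (with provenance
#'   header).
#' @param geometry,thresholds,cvp_target_rate,trim_frac See
#'   [compute_cycle_metrics()] and [summarize_level()].
#' @param quiet Suppress per-segment log messages.
#' @return List with `cycles` (cycle-metrics data.frame, one row per
#'   respiratory cycle across all sequences) and `summaries` (one row per
#'   sequence from [summarize_level()]).
#' @export
run_analyze <- function(study, out_csv = NULL, geometry = doppler_geometry(),
                        thresholds = qc_thresholds(), cvp_target_rate = 40,
                        trim_frac = 0.05, quiet = FALSE) {
  if (is.character(study)) study <- read_study(study)
  stopifnot(inherits(study, "pulsevar_study"))
  ann <- study$annotation
  all_cycles <- list(); all_sum <- list()
  for (i in seq_len(nrow(ann))) {
    rec <- ann[i, ]
    res <- tryCatch({
      seg <- extract_segment(study$subjects[[rec$subject]], rec)
      compute_cycle_metrics(seg, geometry = geometry,
                            thresholds = thresholds,
                            cvp_target_rate = cvp_target_rate)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!quiet)
        message(sprintf("analyze: %s lbnp=%g %s r=%g SKIPPED (%s)",
                        rec$subject, rec$lbnp, rec$intervention,
                        rec$resistance, conditionMessage(res)))
      next
    }
    seg <- extract_segment(study$subjects[[rec$subject]], rec)
    all_cycles[[length(all_cycles) + 1L]] <- res$cycles
    all_sum[[length(all_sum) + 1L]] <-
      summarize_level(res$cycles, res$beats, seg, trim_frac = trim_frac)
    if (!quiet)
      message(sprintf("analyze: %s lbnp=%g %s r=%g: %d cycles, %d accepted%s",
                      rec$subject, rec$lbnp, rec$intervention, rec$resistance,
                      nrow(res$cycles), sum(res$cycles$accepted),
                      if (any(!res$cycles$accepted))
                        paste0(" [", paste(unique(
                          res$cycles$reject_reason[!res$cycles$accepted]),
                          collapse = ","), "]") else ""))
  }
  cycles <- do.call(rbind, all_cycles)
  summaries <- do.call(rbind, all_sum)
  if (!is.null(out_csv) && !is.null(cycles)) {
    dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
    write_results_csv(cycles, out_csv,
                      seed = if (!is.null(study$config)) study$config$rng_seed)
  }
  invisible(list(cycles = cycles, summaries = summaries))
}

#' Fit the slope models and emit tables and figures
#'
#' Fits [pvar_model()] per outcome and intervention on the accepted cycle
#' rows, writes one published-table-shaped CSV per outcome and one figure
#' per outcome/intervention showing the back-transformed model curves with
#' confidence ribbons over LBNP.
#'
#' @param cycles Cycle-metrics data.frame (from [run_analyze()]) or a CSV
#'   path written by it.
#' @param out_dir Output directory for `results_<outcome>.csv` and
#'   `fig_<outcome>_<intervention>.png`; `NULL` writes nothing.
#' @param outcomes Outcomes to model.
#' @param adjust_seed Seed for the single-step adjustment.
#' @param figures Write figures.
#' @param quiet Suppress log messages.
#' @return Named list of fitted `pvar_model` objects
#'   (`"<outcome>.<intervention>"`), invisibly.
#' @export
run_fit <- function(cycles, out_dir = NULL,
                    outcomes = c("dpp", "dpop", "dcvp"),
                    adjust_seed = 104729L, figures = TRUE, quiet = FALSE) {
  if (is.character(cycles)) cycles <- read_results_csv(cycles)
  if (is.null(cycles) || !nrow(cycles))
    stop("no cycle metrics to fit: empty input")
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  models <- list()
  for (oc in outcomes) {
    if (!oc %in% names(cycles) || !any(is.finite(cycles[[oc]]))) {
      if (!quiet) message("fit: outcome ", oc, " absent or all-NA, skipped")
      next
    }
    tabs <- list()
    for (iv in intersect(c("PEP", "CPAP"), unique(cycles$intervention))) {
      m <- tryCatch(pvar_model(cycles, outcome = oc, intervention = iv,
                               adjust_seed = adjust_seed),
                    error = function(e) e)
      if (inherits(m, "error")) {
        if (!quiet) message(sprintf("fit: %s/%s failed (%s)", oc, iv,
                                    conditionMessage(m)))
        next
      }
      models[[paste(oc, iv, sep = ".")]] <- m
      tabs[[iv]] <- results_table(m)
      if (!quiet)
        message(sprintf("fit: %s/%s n=%d subjects=%d%s", oc, iv, m$n_obs,
                        m$n_subjects, if (m$singular) " (singular)" else ""))
      if (!is.null(out_dir) && figures) {
        grDevices::png(file.path(out_dir, sprintf("fig_%s_%s.png", oc, iv)),
                       width = 900, height = 600, res = 120)
        plot(m)
        grDevices::dev.off()
      }
    }
    if (!is.null(out_dir) && length(tabs))
      write_results_csv(do.call(rbind, c(tabs, make.row.names = FALSE)),
                        file.path(out_dir, sprintf("results_%s.csv", oc)),
                        seed = adjust_seed)
  }
  invisible(models)
}

#' Run the whole pipeline: simulate, analyze, fit
#'
#' @param config A [simulation_config()].
#' @param out_dir Root output directory (`dataset/`, `cycles.csv`,
#'   `results/`).
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with `manifest`, `analysis` and `models`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  manifest <- run_simulate(config, file.path(out_dir, "dataset"), quiet = quiet)
  analysis <- run_analyze(file.path(out_dir, "dataset"),
                          out_csv = file.path(out_dir, "cycles.csv"),
                          quiet = quiet)
  models <- run_fit(analysis$cycles, out_dir = file.path(out_dir, "results"),
                    quiet = quiet)
  invisible(list(manifest = manifest, analysis = analysis, models = models))
}
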