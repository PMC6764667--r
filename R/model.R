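#' Mixed-effects slope model for a dynamic variable
#'
#' Fits the linear mixed model
#' `g(y) = b0 + resistance + slope * lbnp_step + (resistance x lbnp_step)
#'  + (1 | subject) + eps`
#' by Gaussian REML, where `y` is one dynamic variable observed per
#' respiratory cycle (or per sequence), `lbnp_step = LBNP / 20` is the
#' hypovolemia step treated as continuous, `resistance` is a factor with
#' reference level 0 cmH2O, and `g` is `log_e` for dPP and dPOP (both are
#' right-skewed on the original scale) and the identity for dCVP (whose
#' published effect sizes are in mmHg per step). The per-resistance-level
#' slope of `g(y)` against the LBNP step — the model's key quantity — is
#' the reference slope plus that level's interaction coefficient.
#'
#' Pairwise slope differences between resistance levels are tested with
#' single-step (max-|z|) multiplicity adjustment via [adjust_single_step()].
#'
#' @param data A data.frame with columns `subject`, `lbnp` (mmHg),
#'   `resistance` (cmH2O) and the outcome column; typically the accepted
#'   rows of a cycle-metrics table.
#' @param outcome Name of the outcome column: `"dpp"`, `"dpop"`, `"dcvp"`,
#'   or any numeric column.
#' @param intervention Optional: restrict to `"PEP"` or `"CPAP"` rows (the
#'   two interventions are modelled separately).
#' @param transform `"auto"` (log for dpp/dpop, identity for dcvp),
#'   `"log"`, or `"identity"`.
#' @param conf_level Confidence level for intervals.
#' @param adjust_draws,adjust_seed Monte Carlo draws and seed for the
#'   single-step adjustment.
#' @param accepted_only Drop cycle rows with `accepted == FALSE` when an
#'   `accepted` column is present.
#' @return An object of class `pvar_model` with `print`, `summary`, `coef`,
#'   `vcov`, `confint`, `predict`, `plot`, `residuals`, `fitted` and
#'   `simulate` methods. Components include `beta`, `vcov`,
#'   `sigma2_subject`, `sigma2_resid`, `slopes`, `contrasts`, `n_obs`,
#'   `n_subjects`, `singular`.
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_subjects = 6, lbnp_levels = c(0, 20, 40),
#'                          interventions = "PEP")
#' tr <- simulate_truth(cfg)
#' tr$dpp <- tr$true_dpp
#' m <- pvar_model(tr, outcome = "dpp", intervention = "PEP")
#' summary(m)
#' }
#' @export
pvar_model <- function(data, outcome = c("dpp", "dpop", "dcvp"),
                       intervention = NULL,
                       transform = c("auto", "log", "identity"),
                       conf_level = 0.95, adjust_draws = 1e5,
                       adjust_seed = 104729L, accepted_only = TRUE) {
  outcome <- outcome[1L]
  transform <- match.arg(transform)
  if (transform == "auto")
    transform <- if (outcome %in% c("dpp", "dpop")) "log" else "identity"
  stopifnot(is.data.frame(data))
  need <- c("subject", "lbnp", "resistance", outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (!is.null(intervention)) {
    if (!"intervention" %in% names(data))
      stop("data has no 'intervention' column to filter on")
    data <- data[data$intervention == intervention, , drop = FALSE]
  }
  if (accepted_only && "accepted" %in% names(data))
    data <- data[data$accepted %in% c(TRUE, NA), , drop = FALSE]
  d <- data.frame(y = data[[outcome]],
                  lbnp_step = data$lbnp / 20,
                  resistance = factor(data$resistance,
                                      levels = sort(unique(data$resistance))),
                  subject = factor(data$subject))
  d <- d[is.finite(d$y), , drop = FALSE]
  if (transform == "log") {
    bad <- d$y <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive outcome value(s) excluded before log transform")
      d <- d[!bad, , drop = FALSE]
    }
    d$y <- log(d$y)
  }
  if (nlevels(droplevels(d$subject)) < 2L) stop("need at least 2 subjects")
  d$subject <- droplevels(d$subject)
  singular <- FALSE
  fit <- withCallingHandlers(
    lme4::lmer(y ~ lbnp_step * resistance + (1 | subject), data = d,
               REML = TRUE),
    message = function(m) {
      if (grepl("singular", conditionMessage(m))) {
        singular <<- TRUE; invokeRestart("muffleMessage")
      }
    })
  if (lme4::isSingular(fit, tol = 1e-5)) singular <- TRUE
  vc <- as.data.frame(lme4::VarCorr(fit))
  obj <- structure(list(
    fit = fit,
    outcome = outcome, transform = transform, intervention = intervention,
    beta = lme4::fixef(fit), vcov = as.matrix(stats::vcov(fit)),
    sigma2_subject = vc$vcov[vc$grp == "subject"],
    sigma2_resid = vc$vcov[vc$grp == "Residual"],
    n_obs = nrow(d), n_subjects = nlevels(d$subject),
    resistance_levels = levels(d$resistance),
    conf_level = conf_level, singular = singular,
    adjust_draws = adjust_draws, adjust_seed = adjust_seed,
    data = d), class = "pvar_model")
  obj$slopes <- slope_estimates(obj)
  obj$contrasts <- slope_contrasts(obj)
  obj
}

# contrast row vector over the fixed effects selecting the slope at one
# resistance level: slope(r) = beta["lbnp_step"] + beta["lbnp_step:resistance r"]
slope_contrast_vector <- function(object, level) {
  nm <- names(object$beta)
  k <- stats::setNames(numeric(length(nm)), nm)
  k["lbnp_step"] <- 1
  inter <- paste0("lbnp_step:resistance", level)
  if (inter %in% nm) k[inter] <- 1
  else if (level != object$resistance_levels[1L])
    stop("no interaction coefficient for resistance level ", level)
  k
}

#' Per-resistance-level slope estimates
#'
#' The slope of the (possibly log-transformed) dynamic variable per LBNP
#' step at each resistance level, with Wald confidence intervals (normal
#' reference).
#'
#' @param object A [pvar_model()].
#' @param conf_level Confidence level; defaults to the model's.
#' @return A data.frame: `resistance`, `slope`, `se`, `lower`, `upper`, `p`.
#' @export
slope_estimates <- function(object, conf_level = object$conf_level) {
  stopifnot(inherits(object, "pvar_model"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(object$resistance_levels, function(r) {
    k <- slope_contrast_vector(object, r)
    est <- sum(k * object$beta)
    se <- sqrt(drop(t(k) %*% object$vcov %*% k))
    data.frame(resistance = r, slope = est, se = se,
               lower = est - z * se, upper = est + z * se,
               p = 2 * stats::pnorm(-abs(est / se)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise slope contrasts between resistance levels
#'
#' Differences of per-level slopes (equivalently, differences of
#' interaction coefficients), with raw normal-reference p-values and
#' single-step adjusted p-values over the whole contrast family.
#'
#' @param object A [pvar_model()].
#' @param conf_level Confidence level; defaults to the model's.
#' @return A data.frame: `contrast`, `estimate`, `se`, `lower`, `upper`,
#'   `p_raw`, `p_adj`.
#' @export
slope_contrasts <- function(object, conf_level = object$conf_level) {
  stopifnot(inherits(object, "pvar_model"))
  lv <- object$resistance_levels
  if (length(lv) < 2L) {
    return(data.frame(contrast = character(0), estimate = numeric(0),
                      se = numeric(0), lower = numeric(0), upper = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0)))
  }
  pairs <- utils::combn(seq_along(lv), 2L)
  K <- t(apply(pairs, 2L, function(ij) {
    slope_contrast_vector(object, lv[ij[2L]]) -
      slope_contrast_vector(object, lv[ij[1L]])
  }))
  rownames(K) <- apply(pairs, 2L, function(ij)
    paste(lv[ij[2L]], "-", lv[ij[1L]]))
  est <- drop(K %*% object$beta)
  V <- K %*% object$vcov %*% t(K)
  adj <- adjust_single_step(est, V, n_draws = object$adjust_draws,
                            seed = object$adjust_seed)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(contrast = rownames(K), estimate = est, se = adj$se,
             lower = est - z * adj$se, upper = est + z * adj$se,
             p_raw = adj$p_raw, p_adj = adj$p_adj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-step (max-|z|) multiplicity adjustment
#'
#' Familywise-error-controlling adjustment using the joint normal
#' distribution of the standardized contrasts: the adjusted p-value of
#' contrast `i` is `P(max_j |Z_j| >= |z_i|)` under a zero-mean multivariate
#' normal with the contrasts' correlation matrix, evaluated by seeded Monte
#' Carlo. Adjusted p-values are clamped to `[p_raw, min(1, m * p_raw)]`
#' (the Bonferroni envelope).
#'
#' @param estimate Vector of contrast estimates.
#' @param vcov Their covariance matrix (repaired by eigenvalue clipping if
#'   numerically non-positive-semidefinite).
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Integer seed (local to this call).
#' @return A data.frame: `estimate`, `se`, `z`, `p_raw`, `p_adj`.
#' @examples
#' # two independent contrasts at z = 1.96: p_adj ~ 1 - (1 - 0.05)^2
#' adjust_single_step(c(1.96, 0.5), diag(2), seed = 1)
#' @export
adjust_single_step <- function(estimate, vcov, n_draws = 1e5, seed = 104729L) {
  vcov <- as.matrix(vcov)
  m <- length(estimate)
  stopifnot(nrow(vcov) == m, ncol(vcov) == m)
  se <- sqrt(diag(vcov))
  if (any(se <= 0)) stop("contrast variances must be positive")
  z <- estimate / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  if (m == 1L) {
    return(data.frame(estimate = estimate, se = se, z = z, p_raw = p_raw,
                      p_adj = p_raw))
  }
  R <- vcov / (se %o% se)
  eg <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-6)
    stop("contrast correlation matrix is not positive semi-definite")
  lam <- pmax(eg$values, 0)  # clip tiny negative eigenvalues
  L <- eg$vectors %*% diag(sqrt(lam), m)
  p_mc <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_draws * m), n_draws, m) %*% t(L)
    maxabs <- do.call(pmax, as.data.frame(abs(Z)))
    vapply(abs(z), function(zi) mean(maxabs >= zi), 0)
  })
  p_adj <- pmin(pmax(p_mc, p_raw), pmin(1, m * p_raw))
  data.frame(estimate = estimate, se = se, z = z, p_raw = p_raw,
             p_adj = p_adj)
}

#' @export
print.pvar_model <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed-effects slope model for %s%s\n",
              x$outcome,
              if (!is.null(x$intervention)) paste0(" (", x$intervention, ")") else ""))
  cat(sprintf("  transform: %s | obs: %d | subjects: %d%s\n",
              x$transform, x$n_obs, x$n_subjects,
              if (x$singular) " | NOTE: singular fit (subject variance at boundary)" else ""))
  cat(sprintf("  variance components: subject %.4g, residual %.4g\n",
              x$sigma2_subject, x$sigma2_resid))
  cat("\nSlopes per LBNP step (20 mmHg) by resistance level:\n")
  print(format_num_df(x$slopes, digits))
  invisible(x)
}

format_num_df <- function(df, digits) {
  for (j in seq_along(df)) if (is.numeric(df[[j]]))
    df[[j]] <- signif(df[[j]], digits)
  df
}

#' @export
summary.pvar_model <- function(object, ...) {
  structure(list(model = object, slopes = object$slopes,
                 contrasts = object$contrasts),
            class = "summary.pvar_model")
}

#' @export
print.summary.pvar_model <- function(x, digits = 3, ...) {
  print(x$model, digits = digits)
  if (nrow(x$contrasts)) {
    cat("\nPairwise slope contrasts (single-step adjusted):\n")
    print(format_num_df(x$contrasts, digits))
  }
  invisible(x)
}

#' @export
coef.pvar_model <- function(object, ...) object$beta

#' @export
vcov.pvar_model <- function(object, ...) object$vcov

#' @export
confint.pvar_model <- function(object, parm, level = 0.95, ...) {
  s <- slope_estimates(object, conf_level = level)
  out <- as.matrix(s[, c("lower", "upper")])
  rownames(out) <- paste0("slope@", s$resistance)
  out
}

#' @export
residuals.pvar_model <- function(object, ...) {
  stats::residuals(object$fit)  # on the transformed (link) scale
}

#' @export
fitted.pvar_model <- function(object, scale = c("response", "link"), ...) {
  f <- stats::fitted(object$fit)
  scale <- match.arg(scale)
  if (scale == "response" && object$transform == "log") exp(f) else f
}

#' Model-implied dynamic-variable curves over LBNP
#'
#' Population-level (fixed-effects) predictions on the response scale with
#' Wald confidence bands; for log-transformed outcomes the curves are
#' back-transformed, hence curved on the original scale.
#'
#' @param object A [pvar_model()].
#' @param newdata Optional data.frame with `lbnp` (mmHg) and `resistance`;
#'   defaults to a grid over the observed range.
#' @param level Confidence level.
#' @param ... Unused.
#' @return `newdata` with columns `fit`, `lwr`, `upr` (response scale).
#' @export
predict.pvar_model <- function(object, newdata = NULL, level = 0.95, ...) {
  if (is.null(newdata)) {
    newdata <- expand.grid(
      lbnp = seq(0, 20 * max(object$data$lbnp_step), by = 5),
      resistance = object$resistance_levels, stringsAsFactors = FALSE)
  }
  d <- data.frame(lbnp_step = newdata$lbnp / 20,
                  resistance = factor(newdata$resistance,
                                      levels = object$resistance_levels))
  X <- stats::model.matrix(~ lbnp_step * resistance, d)
  X <- X[, names(object$beta), drop = FALSE]
  eta <- drop(X %*% object$beta)
  se <- sqrt(rowSums((X %*% object$vcov) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  inv <- if (object$transform == "log") exp else identity
  newdata$fit <- inv(eta)
  newdata$lwr <- inv(eta - z * se)
  newdata$upr <- inv(eta + z * se)
  newdata
}

#' @export
plot.pvar_model <- function(x, lbnp_grid = seq(0, 20 * max(x$data$lbnp_step), 2),
                            level = 0.95, main = NULL, ...) {
  lv <- x$resistance_levels
  nd <- expand.grid(lbnp = lbnp_grid, resistance = lv,
                    stringsAsFactors = FALSE)
  pr <- predict(x, nd, level = level)
  cols <- grDevices::hcl.colors(max(3L, length(lv)), "Dark 3")[seq_along(lv)]
  ylab <- if (x$transform == "log") paste0(x$outcome, " (%)") else
    paste0(x$outcome, " (mmHg)")
  if (is.null(main))
    main <- paste0("Model-implied ", x$outcome,
                   if (!is.null(x$intervention)) paste0(" under ", x$intervention))
  graphics::plot(NA, xlim = range(lbnp_grid), ylim = range(pr$lwr, pr$upr),
                 xlab = "LBNP (mmHg)", ylab = ylab, main = main, ...)
  for (i in seq_along(lv)) {
    p <- pr[pr$resistance == lv[i], ]
    graphics::polygon(c(p$lbnp, rev(p$lbnp)), c(p$lwr, rev(p$upr)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(p$lbnp, p$fit, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = paste0(lv, " cmH2O"), col = cols,
                   lwd = 2, bty = "n", title = "resistance")
  invisible(pr)
}

#' @export
simulate.pvar_model <- function(object, nsim = 1, seed = NULL, ...) {
  sims <- stats::simulate(object$fit, nsim = nsim, seed = seed)
  if (object$transform == "log") sims[] <- lapply(sims, exp)
  sims
}

#' Assemble the published-table-shaped results for one outcome
#'
#' One row per resistance level with that level's slope (CI, p) and its
#' differences to the lower levels (CI, single-step adjusted p) — the
#' triangular layout of the study's effect tables.
#'
#' @param object A [pvar_model()].
#' @return A data.frame with columns `intervention`, `outcome`,
#'   `transform`, `resistance`, `slope`, `slope_lwr`, `slope_upr`, `p`, and
#'   for each lower level `L`: `diff_vs_L`, `diff_vs_L_lwr`,
#'   `diff_vs_L_upr`, `diff_vs_L_p_adj`.
#' @export
results_table <- function(object) {
  stopifnot(inherits(object, "pvar_model"))
  s <- object$slopes; k <- object$contrasts
  lv <- object$resistance_levels
  out <- data.frame(intervention = if (is.null(object$intervention)) NA_character_
                    else object$intervention,
                    outcome = object$outcome, transform = object$transform,
                    resistance = s$resistance, slope = s$slope,
                    slope_lwr = s$lower, slope_upr = s$upper, p = s$p,
                    stringsAsFactors = FALSE)
  for (ref in lv[-length(lv)]) {
    est <- lwr <- upr <- padj <- rep(NA_real_, nrow(out))
    for (i in seq_along(lv)) {
      nm <- paste(lv[i], "-", ref)
      j <- match(nm, k$contrast)
      if (!is.na(j)) {
        est[i] <- k$estimate[j]; lwr[i] <- k$lower[j]; upr[i] <- k$upper[j]
        padj[i] <- k$p_adj[j]
      }
    }
    out[[paste0("diff_vs_", ref)]] <- est
    out[[paste0("diff_vs_", ref, "_lwr")]] <- lwr
    out[[paste0("diff_vs_", ref, "_upr")]] <- upr
    out[[paste0("diff_vs_", ref, "_p_adj")]] <- padj
  }
  out
}

#' Write / read a results table as CSV with a provenance header
#'
#' Header lines start with `#` and record the package version, the seed and
#' the configuration hash; a timestamp line is written only on request so
#' that identical runs produce byte-identical files.
#'
#' @param df A data.frame (e.g. from [results_table()]).
#' @param path Output CSV path.
#' @param seed,config_hash Optional provenance fields.
#' @param timestamp Write a timestamp line (breaks byte-reproducibility).
#' @return `path` invisibly; `read_results_csv()` returns the data.frame.
#' @export
write_results_csv <- function(df, path, seed = NULL, config_hash = NULL,
                              timestamp = FALSE) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pulsevar version: %s",
                     as.character(utils::packageVersion("pulsevar"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config_hash)) writeLines(sprintf("# config_hash: %s", config_hash), con)
  if (timestamp) writeLines(sprintf("# created: %s", format(Sys.time())), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
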