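test_that("noiseless balanced data identify the generating coefficients", {
  tab <- lmm_table(b0 = log(8), slope = 0.1,
                   inter = c("0" = 0, "5" = 0.04, "10" = 0.07),
                   subj_int = c(-0.2, 0.1, 0.05, 0.05))
  m <- suppressWarnings(pvar_model(tab, outcome = "dpp"))  # zero-residual fixture
  s <- m$slopes
  expect_equal(s$slope[s$resistance == "0"], 0.1, tolerance = 1e-6)
  expect_equal(s$slope[s$resistance == "5"], 0.14, tolerance = 1e-6)
  expect_equal(s$slope[s$resistance == "10"], 0.17, tolerance = 1e-6)
  k <- m$contrasts
  expect_equal(k$estimate[k$contrast == "10 - 0"], 0.07, tolerance = 1e-6)

  # zero interactions: identical slope at every level
  tab0 <- lmm_table(inter = c("0" = 0, "5" = 0, "10" = 0),
                    subj_int = c(-0.1, 0.2, 0, 0.1))
  m0 <- suppressWarnings(pvar_model(tab0, outcome = "dpp"))
  expect_lt(diff(range(m0$slopes$slope)), 1e-8)
  expect_lt(max(abs(m0$contrasts$estimate)), 1e-8)
})

test_that("with zero subject variance the fit matches the OLS oracle", {
  tab <- lmm_table(subj_int = rep(0, 6), eps_sd = 0.2, seed = 13)
  m <- pvar_model(tab, outcome = "dpp")
  ols <- lm(log(dpp) ~ I(lbnp / 20) * factor(resistance), data = tab)
  expect_lt(max(abs(unname(coef(m)) - unname(coef(ols)))), 1e-6)
  expect_true(m$singular || m$sigma2_subject < 1e-6)
})

test_that("slope contrasts are antisymmetric differences of interactions", {
  tab <- lmm_table(subj_int = c(0.1, -0.1, 0.2, 0), eps_sd = 0.1, seed = 17)
  m <- pvar_model(tab, outcome = "dpp")
  s <- m$slopes; k <- m$contrasts
  for (nm in k$contrast) {
    lv <- strsplit(nm, " - ")[[1]]
    expect_equal(k$estimate[k$contrast == nm],
                 s$slope[s$resistance == lv[1]] - s$slope[s$resistance == lv[2]],
                 tolerance = 1e-10)
  }
  expect_true(all(k$p_adj >= k$p_raw - 1e-12))
  expect_true(all(k$p_adj <= pmin(1, nrow(k) * k$p_raw) + 1e-12))
})

test_that("single-step adjustment matches closed forms and mvtnorm", {
  # one contrast: adjusted equals raw
  one <- adjust_single_step(2.2, matrix(4), seed = 2)
  expect_equal(one$p_adj, one$p_raw)

  # two independent contrasts: p_adj = 1 - (1 - p_raw)^2
  z <- c(1.959964, 0.8)
  two <- adjust_single_step(z, diag(2), n_draws = 2e5, seed = 3)
  expect_equal(two$p_adj, 1 - (1 - two$p_raw)^2, tolerance = 0.01)

  # perfectly correlated contrasts: adjusted collapses to raw
  R <- matrix(1, 2, 2)
  same <- adjust_single_step(c(1.5, 1.5), R, n_draws = 1e5, seed = 4)
  expect_equal(same$p_adj, same$p_raw, tolerance = 0.01)

  # monotone in |z| for a fixed correlation structure
  V <- matrix(c(1, 0.5, 0.5, 1), 2)
  a <- adjust_single_step(c(1, 2.5), V, n_draws = 1e5, seed = 5)
  expect_lt(a$p_adj[2], a$p_adj[1])

  # against mvtnorm's quasi-Monte-Carlo rectangle probability
  V3 <- matrix(0.4, 3, 3); diag(V3) <- 1
  z3 <- c(0.8, 1.7, 2.6)
  ours <- adjust_single_step(z3, V3, n_draws = 2e5, seed = 6)
  ref <- vapply(z3, function(zi)
    1 - mvtnorm::pmvnorm(lower = rep(-zi, 3), upper = rep(zi, 3),
                         corr = V3)[1], 0)
  expect_equal(ours$p_adj, ref, tolerance = 0.01)
})

test_that("back-transformed predictions are consistent with the slopes", {
  tab <- lmm_table(subj_int = c(0.1, -0.1, 0.2, 0), eps_sd = 0.15, seed = 19)
  m <- pvar_model(tab, outcome = "dpp")
  pr <- predict(m, data.frame(lbnp = c(0, 80, 0, 80),
                              resistance = c(0, 0, 10, 10)))
  s <- m$slopes
  expect_equal(pr$fit[2] / pr$fit[1],
               exp(4 * s$slope[s$resistance == "0"]), tolerance = 1e-8)
  expect_equal(pr$fit[4] / pr$fit[3],
               exp(4 * s$slope[s$resistance == "10"]), tolerance = 1e-8)
  expect_true(all(pr$lwr <= pr$fit & pr$fit <= pr$upr))
})

test_that("model methods behave like a classic fitted-model object", {
  tab <- lmm_table(subj_int = c(0.1, -0.1, 0.2, 0), eps_sd = 0.15, seed = 23)
  m <- pvar_model(tab, outcome = "dpp")
  expect_s3_class(m, "pvar_model")
  expect_named(coef(m)[1], "(Intercept)")
  expect_equal(dim(vcov(m)), c(6L, 6L))
  expect_length(residuals(m), m$n_obs)
  expect_true(all(fitted(m) > 0))   # response scale for a log model
  ci <- confint(m)
  expect_equal(nrow(ci), 3)
  sims <- simulate(m, nsim = 2, seed = 1)
  expect_true(all(unlist(sims) > 0))
  out <- capture.output(print(summary(m)))
  expect_true(any(grepl("Slopes per LBNP step", out)))
  expect_true(any(grepl("single-step", out)))
})

test_that("results tables have the published triangular layout and round-trip", {
  tab <- lmm_table(subj_int = c(0.1, -0.1, 0.2, 0), eps_sd = 0.15, seed = 29)
  m <- pvar_model(tab, outcome = "dpp", intervention = "PEP")
  rt <- results_table(m)
  expect_equal(nrow(rt), 3)
  expect_true(is.na(rt$diff_vs_0[rt$resistance == "0"]))
  expect_false(is.na(rt$diff_vs_0[rt$resistance == "10"]))
  expect_true(is.na(rt$diff_vs_5[rt$resistance == "5"]))

  f <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(rt, f, seed = 42, config_hash = "abc")
  hdr <- readLines(f, n = 3)
  expect_true(any(grepl("# seed: 42", hdr)))
  back <- read_results_csv(f)
  expect_equal(back$slope, rt$slope, tolerance = 1e-12)
  expect_equal(back$diff_vs_0_p_adj, rt$diff_vs_0_p_adj, tolerance = 1e-12)
})

test_that("log transform excludes non-positive outcomes with a warning", {
  tab <- lmm_table(subj_int = rep(0, 4), eps_sd = 0.1, seed = 31)
  tab$dpp[1] <- 0
  expect_warning(m <- pvar_model(tab, outcome = "dpp"), "non-positive")
  expect_equal(m$n_obs, nrow(tab) - 1L)
})
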