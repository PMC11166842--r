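test_that("model lag interpolates the tolerance crossing of a ramp", {
  t <- seq(0, 30, by = 0.5)
  base <- camp_trace(t, rep(0.3, length(t)), condition = "ctrl")
  # difference ramps linearly 0 -> 0.1 over t in [10, 20]
  ramp <- 0.3 + pmin(pmax((t - 10) / 10, 0), 1) * 0.1
  withB <- camp_trace(t, ramp, condition = "org")
  lg <- model_lag(withB, base, tolerance = 0.01, t_ORG = 0)
  expect_true(lg$separated)
  expect_equal(lg$T_S, 11.0, tolerance = 1e-9)
  expect_equal(lg$T_d, 11.0, tolerance = 1e-9)
  # staggered modulator: T_d = T_S - t_ORG
  ramp2 <- 0.3 + pmin(pmax((t - 17.5) / 10, 0), 1) * 0.1  # crosses at 18.5
  lg2 <- model_lag(camp_trace(t, ramp2), base, tolerance = 0.01, t_ORG = 15)
  expect_equal(lg2$T_S, 18.5, tolerance = 1e-9)
  expect_equal(lg2$T_d, 3.5, tolerance = 1e-9)
})

test_that("model lag flags non-separation and rejects mismatched grids", {
  t <- seq(0, 20, 0.5)
  a <- camp_trace(t, sin(t / 10) * 0.001 + 0.3)
  lg <- model_lag(a, a)
  expect_false(lg$separated)
  expect_true(is.na(lg$T_d))
  b <- camp_trace(seq(0, 20, 0.4), rep(0.3, 51))
  expect_error(model_lag(a, b), "identical time grid")
  # a trace falling below the reference never separates
  lo <- camp_trace(t, 0.3 - (t / 20) * 0.2)
  expect_false(model_lag(lo, a)$separated)
})

test_that("plateau/one-phase fit recovers exact data to round-off", {
  t <- seq(0, 30, by = 0.5)
  y <- plateau_assoc(t, Y0 = 0, X0 = 10, plateau = 0.4, K = 0.3)
  fit <- fit_plateau_one_phase(t, y)
  expect_true(fit$converged)
  expect_equal(fit$Y0, 0, tolerance = 1e-6)
  expect_equal(fit$X0, 10, tolerance = 1e-5)
  expect_equal(fit$plateau, 0.4, tolerance = 1e-6)
  expect_equal(fit$K, 0.3, tolerance = 1e-5)
  expect_lt(fit$rss, 1e-12)
})

test_that("flat data are flagged degenerate, short series rejected", {
  t <- seq(0, 10, 1)
  fit <- fit_plateau_one_phase(t, rep(0, length(t)))
  expect_false(fit$converged)
  expect_true(fit$degenerate)
  expect_error(fit_plateau_one_phase(1:5, rnorm(5)), "at least 6")
  expect_error(fit_plateau_one_phase(c(1, 2, 2, 3, 4, 5), rnorm(6)),
               "increasing")
})

test_that("fit recovers onset and rate from noisy pooled replicates", {
  t <- seq(0, 30, by = 0.5)
  truth <- plateau_assoc(t, Y0 = 0, X0 = 10, plateau = 0.4, K = 0.3)
  set.seed(1)
  err_X0 <- err_K <- numeric(100)
  for (s in 1:100) {
    pooled <- (truth + rnorm(length(t), 0, 0.01) +
                 truth + rnorm(length(t), 0, 0.01) +
                 truth + rnorm(length(t), 0, 0.01)) / 3
    fit <- fit_plateau_one_phase(t, pooled)
    err_X0[s] <- abs(fit$X0 - 10) / 10
    err_K[s] <- abs(fit$K - 0.3) / 0.3
  }
  expect_lt(median(err_X0), 0.10)
  expect_lt(median(err_K), 0.10)
})

test_that("experimental lag solves the fitted crossing in closed form", {
  fit <- structure(list(Y0 = 0, X0 = 10, plateau = 0.4, K = 0.3, rss = 0,
                        converged = TRUE, degenerate = FALSE),
                   class = "association_fit")
  lg <- experimental_lag(fit, tolerance = 0.01, t_ORG = 0)
  expect_equal(lg$T_S, 10 + log(0.4 / 0.39) / 0.3, tolerance = 1e-12)
  expect_equal(lg$T_S, 10.0844, tolerance = 1e-4)
  # brute-force oracle: dense-grid crossing of the same curve
  tg <- seq(0, 30, by = 1e-4)
  yg <- plateau_assoc(tg, 0, 10, 0.4, 0.3)
  expect_equal(lg$T_S, tg[which(yg - 0 >= 0.01)[1]], tolerance = 1e-3)

  # plateau below tolerance: never separates
  fit$plateau <- 0.005
  expect_false(experimental_lag(fit, 0.01)$separated)
  # tolerance -> 0+: T_S -> X0
  fit$plateau <- 0.4
  expect_equal(experimental_lag(fit, 1e-12)$T_S, 10, tolerance = 1e-9)
})

test_that("both lag definitions agree on noise-free association-shaped
           traces to within one grid step", {
  step <- 0.5
  t <- seq(0, 30, by = step)
  base <- camp_trace(t, rep(0.25, length(t)))
  for (pars in list(c(X0 = 8, plateau = 0.3, K = 0.2),
                    c(X0 = 14, plateau = 0.12, K = 0.45))) {
    d <- plateau_assoc(t, 0, pars["X0"], pars["plateau"], pars["K"])
    trB <- camp_trace(t, base$values + d)
    lg_m <- model_lag(trB, base, tolerance = 0.01)
    fit <- fit_plateau_one_phase(t, trB$values - base$values)
    lg_e <- experimental_lag(fit, tolerance = 0.01)
    expect_true(lg_m$separated && lg_e$separated)
    expect_lt(abs(lg_m$T_d - lg_e$T_d), step)
  }
})

test_that("lag grows with the separation tolerance for both methods", {
  p <- reference_parameters()
  trB <- sim_trace(p, 1, 0.316, horizon = 30)
  tr0 <- sim_trace(p, 1, 0, horizon = 30)
  tols <- c(0.005, 0.01, 0.02, 0.04)
  td_model <- vapply(tols, function(tl)
    model_lag(trB, tr0, tolerance = tl)$T_d, 0)
  expect_true(all(diff(td_model) > 0))
  keep <- trB$times >= 0
  fit <- fit_plateau_one_phase(trB$times[keep],
                               trB$values[keep] - tr0$values[keep])
  td_exp <- vapply(tols, function(tl)
    experimental_lag(fit, tolerance = tl)$T_d, 0)
  expect_true(all(diff(td_exp) > 0))
})

test_that("experimental estimator recovers the model lag from noisy traces", {
  p <- reference_parameters()
  step <- 0.5
  orgs <- c(0.1, 0.316, 1)
  tr0 <- sim_trace(p, 1, 0, horizon = 30, step = step)
  # fits use the assay's 20-min read window
  keep <- tr0$times >= 0 & tr0$times <= 20
  set.seed(2024)
  for (B in orgs) {
    trB <- sim_trace(p, 1, B, horizon = 30, step = step)
    truth <- model_lag(trB, tr0, tolerance = 0.01)$T_d
    diff_mean <- trB$values[keep] - tr0$values[keep]
    tt <- trB$times[keep]
    est <- numeric(100)
    for (s in 1:100) {
      # technical duplicates x 3 replicates pooled: residual sd 0.01/sqrt(6)
      noisy <- diff_mean + rnorm(length(tt), 0, 0.01 / sqrt(6))
      fit <- fit_plateau_one_phase(tt, noisy)
      est[s] <- if (fit$converged) {
        lg <- experimental_lag(fit, tolerance = 0.01)
        if (lg$separated) lg$T_d else NA_real_
      } else NA_real_
    }
    med <- median(est, na.rm = TRUE)
    expect_lt(abs(med - truth), max(0.5, 0.15 * truth))
  }
})
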