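p_ref <- reference_parameters()

test_that("covariance specs validate symmetry and PSD-ness", {
  mu <- c(agonist.k_int = log(0.15), allosteric.kon3 = log(0.528))
  expect_silent(covariance_spec(mu, diag(0.04, 2)))
  bad <- matrix(c(0.1, 0.3, 0.3, 0.1), 2)  # negative eigenvalue
  expect_error(covariance_spec(mu, bad), "positive semi-definite")
  asym <- matrix(c(0.1, 0.02, 0.03, 0.1), 2)
  expect_error(covariance_spec(mu, asym), "symmetric")
  expect_error(covariance_spec(c(log(0.1), log(0.2)), diag(0.1, 2)),
               "named")
})

test_that("zero covariance reproduces the mean exactly", {
  spec <- covariance_spec(c(agonist.k_int = log(0.15)),
                          matrix(0, 1, 1))
  draws <- sample_parameters(spec, 5, seed = 1, base = p_ref)
  for (d in draws) expect_equal(d$agonist$k_int, 0.15, tolerance = 1e-12)
  expect_identical(attr(draws, "n_rejected"), 0L)
})

test_that("sampler moments match the specification", {
  spec <- demo_covariance_spec(p_ref)
  n <- 10000
  draws <- sample_parameters(spec, n, seed = 3, base = p_ref)
  # recover the estimation-scale (log) values from the parameter sets
  m <- sapply(spec$labels, function(l)
    log(vapply(draws, function(d) param_get(d, l), 0)))
  emp_mean <- colMeans(m)
  emp_cov <- stats::cov(m)
  for (j in seq_along(spec$labels)) {
    se <- sqrt(spec$cov[j, j] / n)
    expect_lt(abs(emp_mean[j] - spec$mean[j]), 3 * se)
    se_var <- spec$cov[j, j] * sqrt(2 / (n - 1))
    expect_lt(abs(emp_cov[j, j] - spec$cov[j, j]), 3 * se_var)
  }
  # off-diagonals are zero in the demo spec; allow 3 MC SEs
  off <- emp_cov[upper.tri(emp_cov)]
  se_off <- sqrt(max(diag(spec$cov))^2 / n)
  expect_true(all(abs(off) < 3 * sqrt(outer(diag(spec$cov),
                                            diag(spec$cov))[upper.tri(emp_cov)] / n) + 1e-12))
})

test_that("identical seeds give bit-identical draws and bands", {
  spec <- demo_covariance_spec(p_ref)
  d1 <- sample_parameters(spec, 20, seed = 11)
  d2 <- sample_parameters(spec, 20, seed = 11)
  expect_identical(d1, d2)
  sched <- standard_schedule(1, 0.1, horizon = 10)
  b1 <- prediction_band(d1, sched, residual_sigma = 0.01, seed = 5)
  b2 <- prediction_band(d2, sched, residual_sigma = 0.01, seed = 5)
  expect_identical(b1, b2)
})

test_that("degenerate bands collapse onto the trajectory", {
  sched <- standard_schedule(1, 0.1, horizon = 10)
  b <- prediction_band(list(p_ref), sched, residual_sigma = 0, seed = 1)
  expect_equal(b$lower, b$median)
  expect_equal(b$upper, b$median)
  traj <- simulate_timecourse(p_ref, sched, grid_step = 0.5)
  expect_equal(b$median, traj$C)
})

test_that("with pure residual noise the band half-width is ~1.96 sigma", {
  spec <- covariance_spec(c(agonist.k_int = log(0.15)), matrix(0, 1, 1))
  draws <- sample_parameters(spec, 5000, seed = 2, base = p_ref)
  sched <- standard_schedule(1, 0, horizon = 10)
  b <- prediction_band(draws, sched, residual_sigma = 0.01, seed = 9)
  half <- (b$upper - b$lower) / 2
  expect_equal(mean(half), 1.96 * 0.01, tolerance = 0.03)
  expect_true(all(abs(half - 1.96 * 0.01) < 0.25 * 1.96 * 0.01))
})

test_that("band width grows with residual sigma and covariance inflation", {
  spec <- covariance_spec(c(agonist.k_int = log(0.15)), matrix(0, 1, 1))
  draws <- sample_parameters(spec, 2000, seed = 2, base = p_ref)
  sched <- standard_schedule(1, 0, horizon = 10)
  b1 <- prediction_band(draws, sched, residual_sigma = 0.01, seed = 9)
  b2 <- prediction_band(draws, sched, residual_sigma = 0.03, seed = 9)
  expect_true(all(b2$upper - b2$lower > b1$upper - b1$lower))

  base_spec <- demo_covariance_spec(p_ref)
  infl <- covariance_spec(base_spec$mean, 4 * base_spec$cov,
                          scale_map = unname(base_spec$scale_map))
  dn <- sample_parameters(base_spec, 400, seed = 4)
  di <- sample_parameters(infl, 400, seed = 4)
  bn <- prediction_band(dn, sched, residual_sigma = 0, seed = 9)
  bi <- prediction_band(di, sched, residual_sigma = 0, seed = 9)
  expect_gt(mean(bi$upper - bi$lower), mean(bn$upper - bn$lower))
})

test_that("higher-level bands nest lower-level bands pointwise", {
  spec <- demo_covariance_spec(p_ref)
  draws <- sample_parameters(spec, 300, seed = 6)
  sched <- standard_schedule(1, 0.1, horizon = 15)
  b95 <- prediction_band(draws, sched, level = 0.95,
                         residual_sigma = 0.01, seed = 7)
  b50 <- prediction_band(draws, sched, level = 0.50,
                         residual_sigma = 0.01, seed = 7)
  expect_true(all(b95$lower <= b50$lower + 1e-12))
  expect_true(all(b95$upper >= b50$upper - 1e-12))
})

test_that("coverage: band median is always inside; self-generated data hit
           ~95%; misspecified data fall out", {
  sched <- standard_schedule(1, 0.1, horizon = 20)
  spec <- demo_covariance_spec(p_ref)
  draws <- sample_parameters(spec, 300, seed = 8)
  band <- prediction_band(draws, sched, residual_sigma = 0.01, seed = 8)

  med <- camp_trace(band$times, band$median, condition = "median")
  cov_med <- coverage_report(med, band)
  expect_equal(cov_med$overall, 1.0)
  expect_true(cov_med$pass)

  # observations drawn from the band's own predictive distribution
  sigma <- 0.01
  hits <- numeric(20)
  for (s in 1:20) {
    pd <- sample_parameters(spec, 1, seed = 100 + s)[[1]]
    traj <- simulate_timecourse(pd, sched, grid_step = 0.5)
    set.seed(200 + s)
    obs <- lapply(1:5, function(r)
      camp_trace(traj$time, traj$C + rnorm(length(traj$C), 0, sigma),
                 condition = sprintf("rep%d", r)))
    hits[s] <- coverage_report(obs, band)$overall
  }
  expect_lt(abs(mean(hits) - 0.95), 0.03)

  # ten-fold faster modulator association pushes observations out of band
  p_mis <- reference_parameters(kon3 = 5.28)
  traj_mis <- simulate_timecourse(p_mis, sched, grid_step = 0.5)
  set.seed(99)
  obs_mis <- camp_trace(traj_mis$time,
                        traj_mis$C + rnorm(length(traj_mis$C), 0, sigma),
                        condition = "mis")
  expect_lt(coverage_report(obs_mis, band)$overall, 0.8)

  expect_error(coverage_report(list(), band), "no observations")
})
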