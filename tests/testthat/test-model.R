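p_ref <- reference_parameters()

test_that("inhibition signal is eps_R*R + eps*AR", {
  expect_equal(inhibition_signal(c(R = 1, AR = 0), p_ref), 1)
  expect_equal(inhibition_signal(c(R = 0, AR = 0), p_ref), 0)
  # printed efficacy: AR = 0.1 alone contributes ~4.57 R0-equivalents
  expect_equal(inhibition_signal(c(R = 0, AR = 0.1), p_ref), 4.57,
               tolerance = 1e-3)
})

test_that("EMAX inhibition is monotone, bounded and hits its half-max", {
  I50 <- p_ref$system$I50
  expect_equal(fractional_inhibition(0, p_ref), 0)
  expect_equal(fractional_inhibition(I50, p_ref),
               p_ref$system$Imax / 2)
  I <- seq(0, 50, length.out = 200)
  f <- fractional_inhibition(I, p_ref)
  expect_true(all(diff(f) > 0))           # strictly increasing
  expect_true(all(f <= p_ref$system$Imax))
  expect_error(fractional_inhibition(-0.1, p_ref), "non-negative")
})

test_that("full model sits still at the drug-free equilibrium", {
  p0 <- reference_parameters(k_syn_R = 0)
  state <- c(R = 1, AR = 0, ARB_T = 0, ARB = 0, RB = 0, R_lost = 0, C = 0)
  d <- full_rhs(state, 0, p0, list(A = 0, B = 0, forskolin = FALSE))[[1]]
  expect_equal(d, rep(0, 7), tolerance = 1e-14)
})

test_that("receptor mass is conserved by both right-hand sides", {
  p0 <- reference_parameters(k_syn_R = 0)
  set.seed(42)
  for (i in 1:5) {
    state <- c(R = runif(1), AR = runif(1), ARB_T = runif(1),
               ARB = runif(1), RB = runif(1), R_lost = runif(1),
               C = runif(1))
    d <- full_rhs(state, 0, p0,
                  list(A = runif(1, 0, 2), B = runif(1, 0, 2),
                       forskolin = TRUE))[[1]]
    expect_equal(sum(d[1:6]), 0, tolerance = 1e-12)
    rstate <- c(U = runif(1), AR = runif(1), W = runif(1),
                R_lost = runif(1), C = runif(1))
    dr <- reduced_rhs(rstate, 0, p0,
                      list(A = runif(1, 0, 2), B = runif(1, 0, 2),
                           forskolin = TRUE))[[1]]
    expect_equal(sum(dr[1:4]), 0, tolerance = 1e-12)
  }
})

test_that("long-time occupancy follows the binding isotherm", {
  # A >> Kd, no internalisation: AR/(R+AR) -> A/(A+Kd)
  p0 <- reference_parameters(k_int = 0, k_int_T = 0)
  A <- 0.5
  traj <- simulate_timecourse(p0, standard_schedule(A, 0, horizon = 20),
                              grid_step = 0.1, method = "full")
  Kd <- derived_quantities(p0)$Kd_uM
  last <- traj[nrow(traj), ]
  expect_equal(last$AR / (last$R + last$AR), A / (A + Kd),
               tolerance = 1e-6)
})

test_that("reduced model degenerates correctly", {
  # B = 0: ternary/modulator pools stay empty, two-species dynamics only
  traj <- simulate_timecourse(p_ref, standard_schedule(1, 0, horizon = 20),
                              grid_step = 0.1)
  expect_true(all(traj$ARB_T == 0) && all(traj$ARB == 0) &&
                all(traj$RB == 0))
  # K_TI_eq = 0: the inactive ternary state never forms
  p0 <- reference_parameters(K_TI_eq = 0)
  traj0 <- simulate_timecourse(p0, standard_schedule(1, 0.3, horizon = 20),
                               grid_step = 0.1)
  expect_true(all(traj0$ARB == 0))
  expect_gt(max(traj0$ARB_T), 0)
})

test_that("reduced trajectories match the full model when the lumped
           reactions equilibrate fast", {
  set.seed(7)
  for (i in 1:10) {
    turnover <- runif(1, 0.01, 0.1)
    p0 <- reference_parameters(
      k_int = runif(1, 0.05, 0.3),
      kon3 = runif(1, 0.1, 1),
      koff3 = runif(1, 0.05, 0.3),
      K_TI_eq = runif(1, 1, 8),
      k_out = turnover, k_in = turnover)
    # fast-equilibration regime: the lumped reactions must be fast relative
    # to agonist binding, not just to internalisation
    pfast <- param_set(p0, list(k_TI = 2000, kon2 = 500))
    A <- runif(1, 0.3, 3); B <- runif(1, 0.1, 1)
    sched <- standard_schedule(A, B, horizon = 20, pre_read = 0)
    full <- simulate_timecourse(pfast, sched, grid_step = 0.2,
                                method = "full")
    red <- simulate_timecourse(pfast, sched, grid_step = 0.2,
                               method = "reduced")
    scale <- max(abs(full$C), 0.1)
    expect_lt(max(abs(full$C - red$C)) / scale, 0.01)
    expect_lt(max(abs(full$AR - red$AR)), 0.01)
  }
})

test_that("pre-equilibrated agonist-only receptor decays exponentially", {
  # with binding >> internalisation the quasi-steady pool decays at
  # k_int * occupancy; start from the occupied quasi-steady state
  p0 <- reference_parameters(kon_A = 1000)
  traj <- simulate_timecourse(p0, standard_schedule(1, 0, horizon = 15),
                              grid_step = 0.05)
  Kd <- derived_quantities(p0)$Kd_uM
  occ <- 1 / (1 + Kd)
  t <- traj$time[traj$time >= 1]
  ar <- traj$AR[traj$time >= 1]
  expect_equal(ar, occ * exp(-p0$agonist$k_int * occ * t),
               tolerance = 0.01)
})

test_that("species and cAMP stay non-negative across shipped scenarios", {
  for (B in c(0, 0.1, 1, 10)) {
    traj <- simulate_timecourse(p_ref, standard_schedule(1, B, horizon = 30),
                                grid_step = 0.2)
    expect_true(all(as.matrix(traj[, -(1:2)]) >= -1e-9))
  }
})

test_that("trajectory-level conservation holds to integrator tolerance", {
  for (method in c("full", "reduced")) {
    traj <- simulate_timecourse(p_ref,
                                standard_schedule(1, 0.316, horizon = 30),
                                grid_step = 0.1, method = method)
    total <- rowSums(traj[, c("R", "AR", "ARB_T", "ARB", "RB", "R_lost")])
    expect_lt(max(abs(total - 1)), 1e-6)
  }
})
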