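# Shared fixtures for the kinetic tests: simulate an observed-scale trace
# for a standard forskolin + agonist (+ modulator) schedule, and compute the
# model-method lag against the matching agonist-alone control.

sim_trace <- function(p, A, B = 0, t_B = 0, horizon = 30, step = 0.1,
                      method = "reduced",
                      condition = sprintf("A%g_B%g", A, B)) {
  observe_trace(
    simulate_timecourse(p, standard_schedule(A, B, t_B = t_B,
                                             horizon = horizon),
                        grid_step = step, method = method),
    condition = condition)
}

lag_vs_control <- function(p, A, B, t_B = 0, horizon = 30, step = 0.1,
                           tolerance = 0.01) {
  model_lag(sim_trace(p, A, B, t_B = t_B, horizon = horizon, step = step),
            sim_trace(p, A, 0, horizon = horizon, step = step),
            tolerance = tolerance, t_ORG = t_B)
}

# First time AR drops below `thr` (linear interpolation), ignoring the
# initial binding transient.
ar_crossing <- function(traj, thr = 0.1) {
  sf <- species_fractions(traj)
  keep <- sf$time > 0.5
  t <- sf$time[keep]; ar <- sf$AR[keep]
  i <- which(ar < thr)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  t[i - 1] + (thr - ar[i - 1]) / (ar[i] - ar[i - 1]) * (t[i] - t[i - 1])
}

# Piecewise plateau-then-association curve (independent reimplementation of
# the fitted model, used as an oracle).
plateau_assoc <- function(t, Y0, X0, plateau, K)
  ifelse(t < X0, Y0, Y0 + (plateau - Y0) * (1 - exp(-K * (t - X0))))
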