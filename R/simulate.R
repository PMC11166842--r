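#' A timed drug addition
#'
#' @param time Minutes from assay read start (t = 0 is the first
#'   post-baseline drug addition); must be >= 0.
#' @param ligand One of `"A"` (orthosteric agonist), `"B"` (allosteric
#'   modulator) or `"forskolin"`.
#' @param concentration Concentration in uM. An event sets the ambient level
#'   of its ligand from `time` onward (free-ligand depletion is ignored).
#'   Forskolin acts as a binary drive: any positive concentration switches
#'   the cAMP production term on.
#' @return A `dose_event`.
#' @export
dose_event <- function(time, ligand, concentration) {
  if (!is.numeric(time) || !is.finite(time) || time < 0)
    stop("event time must be a non-negative number of minutes",
         call. = FALSE)
  ligand <- match.arg(ligand, c("A", "B", "forskolin"))
  if (!is.numeric(concentration) || !is.finite(concentration) ||
      concentration < 0)
    stop("concentration must be non-negative (uM)", call. = FALSE)
  structure(list(time = time, ligand = ligand,
                 concentration = concentration),
            class = "dose_event")
}

#' An experimental dosing schedule
#'
#' @param events List of [dose_event()]s (any order; stored sorted by time).
#' @param horizon Total simulated minutes after t = 0; must be at least the
#'   last event time.
#' @param pre_read Minutes of drug-free baseline read before the first
#'   addition (simulated at negative times).
#' @return A `dose_schedule`.
#' @export
#' @examples
#' co_addition <- dose_schedule(list(
#'   dose_event(0, "forskolin", 5),
#'   dose_event(0, "A", 1),
#'   dose_event(0, "B", 0.1)
#' ), horizon = 30)
dose_schedule <- function(events, horizon, pre_read = 5) {
  if (inherits(events, "dose_event")) events <- list(events)
  if (!length(events) || !all(vapply(events, inherits, TRUE, "dose_event")))
    stop("events must be a non-empty list of dose_event objects",
         call. = FALSE)
  times <- vapply(events, `[[`, 0, "time")
  events <- events[order(times)]
  if (!is.numeric(horizon) || horizon < max(times))
    stop("horizon (", horizon, " min) must be >= the last event time (",
         max(times), " min)", call. = FALSE)
  if (!is.numeric(pre_read) || pre_read < 0)
    stop("pre_read must be non-negative minutes", call. = FALSE)
  structure(list(events = events, horizon = horizon, pre_read = pre_read),
            class = "dose_schedule")
}

#' Convenience schedule: agonist/modulator/forskolin additions
#'
#' Builds the assay's standard schedules: forskolin plus agonist at t = 0,
#' with the modulator either co-added at t = 0 or staggered to `t_B`.
#'
#' @param A_uM,B_uM Agonist and modulator concentrations (uM); zero omits the
#'   addition.
#' @param t_B Modulator addition time (min).
#' @param horizon,pre_read See [dose_schedule()].
#' @return A `dose_schedule`.
#' @export
standard_schedule <- function(A_uM, B_uM = 0, t_B = 0, horizon = 30,
                              pre_read = 5) {
  ev <- list(dose_event(0, "forskolin", 5))
  if (A_uM > 0) ev <- c(ev, list(dose_event(0, "A", A_uM)))
  if (B_uM > 0) ev <- c(ev, list(dose_event(t_B, "B", B_uM)))
  dose_schedule(ev, horizon = horizon, pre_read = pre_read)
}

## Piecewise-constant ambient ligand levels implied by a schedule.
schedule_segments <- function(schedule) {
  stopifnot(inherits(schedule, "dose_schedule"))
  ev_times <- vapply(schedule$events, `[[`, 0, "time")
  breaks <- sort(unique(c(0, ev_times)))
  starts <- c(-schedule$pre_read, breaks)
  ends <- c(breaks, schedule$horizon)
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  segs <- data.frame(start = starts, end = ends, A = NA_real_,
                     B = NA_real_, fsk = NA)
  for (i in seq_along(starts)) {
    ## an event sets its ligand's ambient level from its time onward;
    ## the latest event per ligand at or before the segment start wins
    A <- B <- 0; fsk <- FALSE
    if (starts[i] >= 0)
      for (e in schedule$events)
        if (e$time <= starts[i]) {
          if (e$ligand == "A") A <- e$concentration
          if (e$ligand == "B") B <- e$concentration
          if (e$ligand == "forskolin") fsk <- e$concentration > 0
        }
    segs$A[i] <- A; segs$B[i] <- B; segs$fsk[i] <- fsk
  }
  segs$label <- ifelse(segs$start < 0, "pre_read",
                       sprintf("seg%02d", cumsum(segs$start >= 0)))
  segs
}

#' Simulate the model over a dosing schedule
#'
#' Integrates the reduced (default) or full model with `deSolve::lsoda`
#' (stiff-capable, rtol 1e-8, atol 1e-10), restarting the integration at
#' every dose event so that concentration steps are handled exactly. The
#' initial condition is all receptor free (`R = R0`) with cAMP at its
#' drug-free steady state (0 on the normalised scale). The pre-read window
#' is simulated at negative times with no drugs present.
#'
#' @param p A `parameter_set`.
#' @param schedule A `dose_schedule`.
#' @param grid_step Output grid step in minutes (> 0). Event times are
#'   always grid points.
#' @param method `"reduced"` (quasi-equilibrium, default) or `"full"`.
#' @return A `cb_trajectory`: data frame with columns `time`, `segment` and
#'   the full species set `R, AR, ARB_T, ARB, RB, R_lost, C` (reduced-model
#'   runs are expanded through the quasi-equilibrium partition), carrying the
#'   schedule, parameters and method as attributes.
#' @export
#' @examples
#' p <- reference_parameters()
#' traj <- simulate_timecourse(p, standard_schedule(1, 0.1), grid_step = 0.5)
#' head(traj)
simulate_timecourse <- function(p, schedule, grid_step = 0.1,
                                method = c("reduced", "full")) {
  stopifnot(inherits(p, "parameter_set"), inherits(schedule, "dose_schedule"))
  if (!is.numeric(grid_step) || grid_step <= 0)
    stop("grid_step must be positive minutes", call. = FALSE)
  method <- match.arg(method)
  k <- rhs_constants(p)
  segs <- schedule_segments(schedule)
  if (method == "reduced") {
    y <- c(U = p$system$R0, AR = 0, W = 0, R_lost = 0, C = 0)
    fn <- function(t, y, parms) reduced_rhs_raw(t, y, k, parms$A, parms$B,
                                                parms$fsk)
  } else {
    y <- c(R = p$system$R0, AR = 0, ARB_T = 0, ARB = 0, RB = 0,
           R_lost = 0, C = 0)
    fn <- function(t, y, parms) full_rhs_raw(t, y, k, parms$A, parms$B,
                                             parms$fsk)
  }
  out <- NULL
  for (i in seq_len(nrow(segs))) {
    tt <- seq(segs$start[i], segs$end[i], by = grid_step)
    if (max(tt) < segs$end[i]) tt <- c(tt, segs$end[i])
    sol <- tryCatch(
      deSolve::lsoda(y, tt, fn,
                     parms = list(A = segs$A[i], B = segs$B[i],
                                  fsk = segs$fsk[i]),
                     rtol = 1e-8, atol = 1e-10),
      warning = function(w) stop("integration failed in segment '",
                                 segs$label[i], "' (", segs$start[i], "-",
                                 segs$end[i], " min): ",
                                 conditionMessage(w), call. = FALSE),
      error = function(e) stop("integration failed in segment '",
                               segs$label[i], "' (", segs$start[i], "-",
                               segs$end[i], " min): ",
                               conditionMessage(e), call. = FALSE))
    y <- sol[nrow(sol), -1]
    states <- sol[, -1, drop = FALSE]
    df <- if (method == "reduced")
      expand_reduced_states(states, k, segs$B[i]) else as.data.frame(states)
    df <- cbind(time = sol[, 1], segment = segs$label[i], df)
    ## boundary point belongs to the later (post-addition) segment
    if (!is.null(out)) out <- out[-nrow(out), , drop = FALSE]
    out <- rbind(out, df)
  }
  rownames(out) <- NULL
  structure(out, class = c("cb_trajectory", "data.frame"),
            schedule = schedule, params = p, method = method,
            grid_step = grid_step)
}

#' Receptor species as fractions of R0
#'
#' @param traj A `cb_trajectory`.
#' @return Data frame with `time`, each species normalised by R0 and the
#'   total remaining surface receptor (`surface_total`).
#' @export
species_fractions <- function(traj) {
  stopifnot(inherits(traj, "cb_trajectory"))
  R0 <- attr(traj, "params")$system$R0
  sp <- c("R", "AR", "ARB_T", "ARB", "RB", "R_lost")
  out <- traj[, c("time", sp)]
  out[sp] <- out[sp] / R0
  out$surface_total <- rowSums(out[c("R", "AR", "ARB_T", "ARB", "RB")])
  out
}

#' Map a trajectory onto the observed (inverse-BRET-like) scale
#'
#' @param traj A `cb_trajectory`.
#' @param baseline Additive offset (response units).
#' @param fsk_efficacy Multiplicative forskolin efficacy scale (> 0).
#' @param condition Condition label stored with the trace.
#' @return A [camp_trace()] with `values = baseline + fsk_efficacy * C(t)`.
#' @export
observe_trace <- function(traj, baseline = 0, fsk_efficacy = 1,
                          condition = "trace") {
  stopifnot(inherits(traj, "cb_trajectory"))
  if (!is.numeric(fsk_efficacy) || fsk_efficacy <= 0)
    stop("fsk_efficacy must be positive", call. = FALSE)
  camp_trace(times = traj$time,
             values = baseline + fsk_efficacy * traj$C,
             condition = condition, baseline = baseline,
             fsk_efficacy = fsk_efficacy,
             segment = traj$segment,
             schedule = attr(traj, "schedule"))
}

#' An observed-scale kinetic cAMP trace
#'
#' @param times Minutes (strictly increasing).
#' @param values Observed-scale response values (finite, same length).
#' @param condition Condition label.
#' @param baseline,fsk_efficacy The offset/scale used to map model output
#'   onto the observed scale (recorded as metadata).
#' @param segment Optional per-point segment labels.
#' @param schedule Optional `dose_schedule` the trace arose from.
#' @return A `camp_trace`.
#' @export
camp_trace <- function(times, values, condition = "trace", baseline = 0,
                       fsk_efficacy = 1, segment = NULL, schedule = NULL) {
  if (length(times) != length(values))
    stop("times and values must have the same length", call. = FALSE)
  if (any(!is.finite(values)) || any(!is.finite(times)))
    stop("times and values must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values, condition = condition,
                 baseline = baseline, fsk_efficacy = fsk_efficacy,
                 segment = segment, schedule = schedule),
            class = "camp_trace")
}

#' @export
print.camp_trace <- function(x, ...) {
  cat("camp_trace '", x$condition, "': ", length(x$times), " points, t = ",
      min(x$times), "..", max(x$times), " min, baseline ", x$baseline,
      ", fsk_efficacy ", x$fsk_efficacy, "\n", sep = "")
  invisible(x)
}

#' @export
print.cb_trajectory <- function(x, ...) {
  cat("cb_trajectory (", attr(x, "method"), " model): ", nrow(x),
      " time points, t = ", min(x$time), "..", max(x$time), " min\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}
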