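#' The shipped orthosteric agonist library
#'
#' Per-agonist overrides of the three orthosteric-ligand-specific parameters
#' (pKd, k_int, log10_eps) and, where a calibrated value exists, the
#' modulator association rate kon3. `"CP"` (the reference agonist CP55940)
#' carries no overrides; `"WIN"` (WIN55,212-2) and `"THC"` keep kon3 fixed at
#' the CP value; `"THC_calibrated"` carries the ten-fold lower kon3 = 0.05
#' obtained by calibration against cAMP traces (probe dependence).
#'
#' @param path Optional path to an alternative agonist JSON file.
#' @return An `agonist_library` (named list of entries with `citation` and
#'   `overrides`).
#' @export
agonist_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "params", "agonists.json",
                        package = "allocamp", mustWork = TRUE)
  lib <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (anyDuplicated(names(lib)))
    stop("agonist names must be unique", call. = FALSE)
  structure(lib, class = "agonist_library")
}

#' Parameter set for a named agonist
#'
#' Starts from [reference_parameters()] and replaces only the agonist-
#' specific parameters (and kon3 when the library entry carries one).
#'
#' @param name Agonist label in the library (e.g. `"CP"`, `"WIN"`, `"THC"`,
#'   `"THC_calibrated"`).
#' @param library An [agonist_library()].
#' @return A `parameter_set`.
#' @export
#' @examples
#' agonist_overrides("WIN")$agonist$log10_eps  # 2.63
agonist_overrides <- function(name, library = agonist_library()) {
  stopifnot(inherits(library, "agonist_library"))
  if (!name %in% names(library))
    stop("unknown agonist '", name, "'; known agonists: ",
         paste(names(library), collapse = ", "), call. = FALSE)
  ov <- library[[name]]$overrides
  p <- reference_parameters()
  if (!length(ov)) return(p)
  allowed <- c("pKd", "k_int", "log10_eps", "kon3")
  bad <- setdiff(names(ov), allowed)
  if (length(bad))
    stop("agonist entries may only override ",
         paste(allowed, collapse = ", "), "; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  prov <- ifelse(names(ov) == "kon3" & name == "THC_calibrated",
                 "calibrated", "printed")
  for (i in seq_along(ov))
    p <- param_set(p, ov[i], provenance = prov[i])
  p
}

#' Grid calibration of the modulator association rate kon3
#'
#' Simulates every candidate kon3 under each target trace's schedule, aligns
#' the simulation to the target by a per-trace linear baseline/efficacy fit
#' (ordinary least squares of the target on the simulated curve), and sums
#' squared discrepancies. The grid value with the lowest summed loss wins;
#' exact ties break toward the smaller kon3.
#'
#' @param target_traces List of [camp_trace()]s, each carrying the
#'   `dose_schedule` it was measured under (as produced by
#'   [observe_trace()] or [generate_dataset()] condition means).
#' @param candidate_grid Candidate kon3 values (1/uM/min); default 21
#'   log-spaced values in `[0.005, 5]`.
#' @param p Base `parameter_set`.
#' @param grid_step Simulation step (min).
#' @param method Model form.
#' @return A `kon3_calibration`: list with `kon3`, `grid`, `loss` (the full
#'   loss profile) and `params` (the base set with kon3 replaced).
#' @export
calibrate_kon3 <- function(target_traces,
                           candidate_grid = 10^seq(log10(0.005), log10(5),
                                                   length.out = 21),
                           p = reference_parameters(), grid_step = 0.25,
                           method = "reduced") {
  if (!length(target_traces))
    stop("target_traces must be non-empty", call. = FALSE)
  if (!length(candidate_grid))
    stop("candidate_grid must be non-empty", call. = FALSE)
  stopifnot(all(vapply(target_traces, inherits, TRUE, "camp_trace")))
  for (tr in target_traces)
    if (is.null(tr$schedule))
      stop("every target trace must carry its dose_schedule", call. = FALSE)
  candidate_grid <- sort(candidate_grid)
  loss <- vapply(candidate_grid, function(k3) {
    pk <- param_set(p, list(kon3 = k3))
    total <- 0
    for (tr in target_traces) {
      sim <- simulate_timecourse(pk, tr$schedule, grid_step = grid_step,
                                 method = method)
      simv <- stats::approx(sim$time, sim$C, xout = tr$times)$y
      ## align experiment-specific baseline and forskolin efficacy
      fit <- stats::lm.fit(cbind(1, simv), tr$values)
      total <- total + sum(fit$residuals^2)
    }
    total
  }, 0)
  best <- which(loss <= min(loss) + 1e-12)[1]  # ties -> smaller kon3
  structure(list(kon3 = candidate_grid[best], grid = candidate_grid,
                 loss = loss,
                 params = param_set(p, list(kon3 = candidate_grid[best]))),
            class = "kon3_calibration")
}

#' @export
print.kon3_calibration <- function(x, ...) {
  cat(sprintf("kon3 calibration: best kon3 = %.4g /uM/min over %d candidates (loss %.4g)\n",
              x$kon3, length(x$grid), min(x$loss)))
  invisible(x)
}

#' Compare signalling profiles across agonists
#'
#' Simulates each agonist under an identical modulator/forskolin schedule,
#' computes the model-method kinetic lag against the matching agonist-alone
#' control, and flags inverse agonism (late-time trace above the
#' forskolin-alone trace, averaged over the last 10% of the read).
#'
#' @param agonists Character vector of agonist labels.
#' @param schedule A `dose_schedule` containing the modulator (and
#'   forskolin) events; the agonist-alone control and forskolin-alone
#'   reference are derived from it by dropping B (and A) events.
#' @param tolerance Separation tolerance for the lag (default 0.01).
#' @param grid_step Simulation step (min).
#' @param library Agonist library.
#' @return Data frame with one row per agonist: `agonist`, `T_S`, `T_d`,
#'   `separated`, `inverse_agonism`, `error` (NA unless the simulation for
#'   that agonist failed; failures do not abort the batch).
#' @export
compare_profiles <- function(agonists, schedule, tolerance = 0.01,
                             grid_step = 0.1, library = agonist_library()) {
  stopifnot(inherits(schedule, "dose_schedule"))
  drop_ligand <- function(sch, drop) {
    ev <- Filter(function(e) !(e$ligand %in% drop), sch$events)
    if (!length(ev)) ev <- list(dose_event(0, "forskolin", 0))
    dose_schedule(ev, horizon = sch$horizon, pre_read = sch$pre_read)
  }
  ctrl_sched <- drop_ligand(schedule, "B")
  fsk_sched <- drop_ligand(schedule, c("A", "B"))
  t_B <- vapply(Filter(function(e) e$ligand == "B", schedule$events),
                `[[`, 0, "time")
  t_ORG <- if (length(t_B)) min(t_B) else 0
  late <- function(tr) {
    n <- length(tr$times)
    mean(tr$values[tr$times >= max(tr$times) - 0.1 *
                     (max(tr$times) - min(tr$times))])
  }
  rows <- lapply(agonists, function(nm) {
    res <- tryCatch({
      p <- agonist_overrides(nm, library = library)
      tr_b <- observe_trace(simulate_timecourse(p, schedule, grid_step),
                            condition = paste0(nm, "+B"))
      tr_0 <- observe_trace(simulate_timecourse(p, ctrl_sched, grid_step),
                            condition = nm)
      tr_f <- observe_trace(simulate_timecourse(p, fsk_sched, grid_step),
                            condition = "forskolin")
      lg <- model_lag(tr_b, tr_0, tolerance = tolerance, t_ORG = t_ORG)
      data.frame(agonist = nm, T_S = lg$T_S, T_d = lg$T_d,
                 separated = lg$separated,
                 inverse_agonism = late(tr_b) > late(tr_f),
                 error = NA_character_)
    }, error = function(e)
      data.frame(agonist = nm, T_S = NA_real_, T_d = NA_real_,
                 separated = NA, inverse_agonism = NA,
                 error = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}
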