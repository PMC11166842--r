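#' A plate-style kinetic experiment design
#'
#' Describes the conditions, replication structure and noise model of a
#' CAMYEL-style kinetic BRET plate: independent replicates carry their own
#' baseline offset and forskolin efficacy scale (emulating between-
#' experiment adjustment); technical duplicates share those but have
#' independent residual noise.
#'
#' @param conditions Data frame with columns `agonist` (library label),
#'   `A_uM`, `B_uM`, `forskolin` (logical) and `t_B` (modulator addition
#'   time, min). A `condition` label column is added when absent.
#' @param n_replicates Independent replicate runs (default 3).
#' @param n_duplicates Technical duplicates per replicate (default 2).
#' @param read_interval Plate read cadence in minutes (default 0.5).
#' @param horizon Read duration after t = 0 (min); lag designs need >= 20.
#' @param pre_read Baseline read before drug addition (min, default 5).
#' @param baseline_sd SD of the per-replicate additive baseline
#'   (Normal(0, 0.02) by default).
#' @param efficacy_sd SD of the per-replicate forskolin efficacy scale
#'   (Normal(1, 0.05), truncated positive).
#' @param residual_sigma SD of the additive Gaussian residual per
#'   observation (default 0.01 on the normalised response scale).
#' @return An `experiment_design`.
#' @export
experiment_design <- function(conditions, n_replicates = 3,
                              n_duplicates = 2, read_interval = 0.5,
                              horizon = 30, pre_read = 5,
                              baseline_sd = 0.02, efficacy_sd = 0.05,
                              residual_sigma = 0.01) {
  need <- c("agonist", "A_uM", "B_uM", "forskolin", "t_B")
  if (!all(need %in% names(conditions)))
    stop("conditions needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (n_replicates < 1 || n_duplicates < 1 || read_interval <= 0)
    stop("replicate/duplicate counts must be >= 1 and read_interval > 0",
         call. = FALSE)
  if (any(conditions$B_uM > 0) && horizon < 20)
    stop("designs containing the modulator need a horizon of >= 20 min ",
         "for lag estimation", call. = FALSE)
  if (!"condition" %in% names(conditions))
    conditions$condition <- sprintf(
      "%s_A%g_B%g_tB%g_fsk%d", conditions$agonist, conditions$A_uM,
      conditions$B_uM, conditions$t_B, as.integer(conditions$forskolin))
  if (anyDuplicated(conditions$condition))
    stop("condition labels must be unique", call. = FALSE)
  structure(list(conditions = conditions, n_replicates = n_replicates,
                 n_duplicates = n_duplicates, read_interval = read_interval,
                 horizon = horizon, pre_read = pre_read,
                 baseline_sd = baseline_sd, efficacy_sd = efficacy_sd,
                 residual_sigma = residual_sigma),
            class = "experiment_design")
}

#' Shipped preset experiment designs
#'
#' * `"validation"`: CP55940 at 0, 0.001, 0.01, 0.1, 1, 10 uM crossed with
#'   modulator at 0, 0.1, 1, 10 uM (24 conditions, all with forskolin,
#'   co-addition, 20-min read).
#' * `"preincubation"`: 1 uM CP55940 with modulator at 0.1, 0.316, 1 uM,
#'   each under co-addition and agonist-15-min-prior schedules, plus the
#'   agonist-alone and forskolin-alone references (35-min read).
#' * `"probe"`: agonists CP, WIN, THC (1 uM) crossed with modulator at 0,
#'   0.1, 1 uM (30-min read).
#'
#' @param name One of `"validation"`, `"preincubation"`, `"probe"`.
#' @return An `experiment_design`.
#' @export
preset_design <- function(name = c("validation", "preincubation", "probe")) {
  name <- match.arg(name)
  if (name == "validation") {
    g <- expand.grid(A_uM = c(0, 0.001, 0.01, 0.1, 1, 10),
                     B_uM = c(0, 0.1, 1, 10))
    cond <- data.frame(agonist = "CP", A_uM = g$A_uM, B_uM = g$B_uM,
                       forskolin = TRUE, t_B = 0)
    return(experiment_design(cond, horizon = 20))
  }
  if (name == "preincubation") {
    g <- expand.grid(B_uM = c(0.1, 0.316, 1), t_B = c(0, 15))
    cond <- data.frame(agonist = "CP", A_uM = 1, B_uM = g$B_uM,
                       forskolin = TRUE, t_B = g$t_B)
    cond <- rbind(cond,
                  data.frame(agonist = "CP", A_uM = c(1, 0), B_uM = 0,
                             forskolin = TRUE, t_B = 0))
    return(experiment_design(cond, horizon = 35))
  }
  g <- expand.grid(agonist = c("CP", "WIN", "THC"), B_uM = c(0, 0.1, 1),
                   stringsAsFactors = FALSE)
  cond <- data.frame(agonist = g$agonist, A_uM = 1, B_uM = g$B_uM,
                     forskolin = TRUE, t_B = 0)
  experiment_design(cond, horizon = 30)
}

condition_schedule <- function(row, design) {
  ev <- list()
  if (row$forskolin) ev <- c(ev, list(dose_event(0, "forskolin", 5)))
  if (row$A_uM > 0) ev <- c(ev, list(dose_event(0, "A", row$A_uM)))
  if (row$B_uM > 0) ev <- c(ev, list(dose_event(row$t_B, "B", row$B_uM)))
  if (!length(ev)) ev <- list(dose_event(0, "forskolin", 0))
  dose_schedule(ev, horizon = design$horizon, pre_read = design$pre_read)
}

condition_params <- function(agonist, p, library) {
  if (agonist == "CP") return(p)
  if (!agonist %in% names(library))
    stop("unknown agonist '", agonist, "' in design", call. = FALSE)
  ov <- library[[agonist]]$overrides
  if (length(ov)) p <- param_set(p, ov, provenance = "printed")
  p
}

#' Generate a synthetic plate dataset
#'
#' Simulates every condition of the design once (deterministic mean curve),
#' then applies per-replicate baseline and forskolin-efficacy draws and
#' per-observation Gaussian residual noise. Identical `(design, p, seed)`
#' inputs regenerate the table bit-exactly.
#'
#' @param design An [experiment_design()].
#' @param p True `parameter_set` for the reference agonist; non-CP
#'   conditions apply the library's agonist overrides on top of it.
#' @param seed Integer seed.
#' @param method Model form passed to [simulate_timecourse()].
#' @param library Agonist library resolving non-CP condition labels.
#' @return A `plate_dataset`: long data frame (`condition`, `replicate`,
#'   `duplicate`, `time_min`, `value`) with the design, true parameters and
#'   seed attached as attributes.
#' @export
generate_dataset <- function(design, p = reference_parameters(), seed,
                             method = "reduced",
                             library = agonist_library()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(p, "parameter_set"))
  if (missing(seed) || !is.numeric(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  set.seed(seed)
  ## each replicate is an independent plate run: its baseline offset and
  ## forskolin efficacy are shared by every condition on that plate
  baselines <- stats::rnorm(design$n_replicates, 0, design$baseline_sd)
  effs <- vapply(seq_len(design$n_replicates), function(r) {
    e <- stats::rnorm(1, 1, design$efficacy_sd)
    while (e <= 0) e <- stats::rnorm(1, 1, design$efficacy_sd)
    e
  }, 0)
  cond <- design$conditions[order(design$conditions$condition), ]
  out <- vector("list", nrow(cond))
  for (ci in seq_len(nrow(cond))) {
    row <- cond[ci, ]
    pc <- condition_params(row$agonist, p, library)
    sched <- condition_schedule(row, design)
    traj <- tryCatch(
      simulate_timecourse(pc, sched, grid_step = design$read_interval,
                          method = method),
      error = function(e) stop("simulation failed for condition '",
                               row$condition, "': ", conditionMessage(e),
                               call. = FALSE))
    mu <- traj$C
    reps <- vector("list", design$n_replicates)
    for (r in seq_len(design$n_replicates)) {
      baseline <- baselines[r]
      eff <- effs[r]
      dups <- vector("list", design$n_duplicates)
      for (d in seq_len(design$n_duplicates)) {
        noise <- if (design$residual_sigma > 0)
          stats::rnorm(length(mu), 0, design$residual_sigma) else 0
        dups[[d]] <- data.frame(condition = row$condition, replicate = r,
                                duplicate = d, time_min = traj$time,
                                value = baseline + eff * mu + noise)
      }
      reps[[r]] <- do.call(rbind, dups)
    }
    out[[ci]] <- do.call(rbind, reps)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  structure(df, class = c("plate_dataset", "data.frame"),
            design = design, params = p, seed = seed)
}

#' Condition-mean traces of a plate dataset
#'
#' Averages replicates and duplicates per condition and returns
#' [camp_trace()]s (each carrying its schedule), the natural input for the
#' lag and calibration pipelines.
#'
#' @param dataset A `plate_dataset`.
#' @return Named list of `camp_trace`s.
#' @export
dataset_means <- function(dataset) {
  stopifnot(inherits(dataset, "plate_dataset"))
  design <- attr(dataset, "design")
  conds <- sort(unique(dataset$condition))
  out <- lapply(conds, function(cn) {
    sub <- dataset[dataset$condition == cn, ]
    agg <- stats::aggregate(value ~ time_min, data = sub, FUN = mean)
    agg <- agg[order(agg$time_min), ]
    row <- design$conditions[design$conditions$condition == cn, ]
    camp_trace(agg$time_min, agg$value, condition = cn,
               schedule = condition_schedule(row, design))
  })
  names(out) <- conds
  out
}
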