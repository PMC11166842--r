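## File I/O: long-format trace CSV (UTF-8, header, minutes, decimal point),
## plate-dataset CSV, lag tables, and the pipeline runner.

#' Write kinetic traces to long-format CSV
#'
#' Columns: `condition, segment, time_min, variable, value`. Conditions are
#' written in lexicographic order, times ascending, so diffs are meaningful.
#'
#' @param traces A `camp_trace` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "camp_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, TRUE, "camp_trace")))
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(condition = tr$condition,
               segment = tr$segment %||% "seg01",
               time_min = tr$times, variable = "response",
               value = tr$values)))
  df <- df[order(df$condition, df$time_min), ]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read kinetic traces from long-format CSV
#'
#' @param path CSV written by [write_traces()].
#' @return Named list of [camp_trace()]s; the write/read round trip is
#'   lossless for times, values and condition labels.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, fileEncoding = "UTF-8"),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  need <- c("condition", "segment", "time_min", "variable", "value")
  if (!nrow(df)) stop("empty trace file: ", path, call. = FALSE)
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$time_min) || !is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value)))) + 1L
    stop("non-numeric time/value entries in '", path, "' (lines ",
         paste(utils::head(bad, 5), collapse = ", "), ")", call. = FALSE)
  }
  conds <- sort(unique(df$condition))
  out <- lapply(conds, function(cn) {
    sub <- df[df$condition == cn, ]
    if (any(diff(sub$time_min) <= 0)) {
      bad <- which(diff(sub$time_min) <= 0)[1]
      line <- as.integer(rownames(sub)[bad + 1]) + 1L
      stop("non-monotone times within condition '", cn, "' near line ",
           line, " of ", path, call. = FALSE)
    }
    camp_trace(sub$time_min, sub$value, condition = cn,
               segment = sub$segment)
  })
  names(out) <- conds
  out
}

#' Write / read a plate dataset CSV
#'
#' @param dataset A `plate_dataset` (or its long data frame).
#' @param path CSV path.
#' @return `write_dataset`: `path` invisibly. `read_dataset`: the long data
#'   frame (columns `condition, replicate, duplicate, time_min, value`);
#'   the round trip reproduces the table exactly.
#' @export
write_dataset <- function(dataset, path) {
  need <- c("condition", "replicate", "duplicate", "time_min", "value")
  stopifnot(all(need %in% names(dataset)))
  utils::write.csv(as.data.frame(dataset)[need], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("condition", "replicate", "duplicate", "time_min", "value")
  if (!all(need %in% names(df)))
    stop("dataset CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Export a lag table to CSV
#' @param results Named list of `lag_result`s or a [lag_table()] data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_lag_table <- function(results, path) {
  df <- if (is.data.frame(results)) results else lag_table(results)
  df <- df[order(df$condition, df$method), ]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

## ---- pipeline runner ------------------------------------------------------

validate_config <- function(config, required, numeric_fields = character()) {
  problems <- character()
  for (f in required)
    if (is.null(config[[f]]))
      problems <- c(problems, paste0("missing required field '", f, "'"))
  for (f in intersect(numeric_fields, names(config)))
    if (!is.numeric(config[[f]]))
      problems <- c(problems, paste0("field '", f, "' must be numeric"))
  if (length(problems))
    stop("configuration is invalid:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

config_design <- function(config) {
  if (!is.null(config$design_preset))
    return(preset_design(config$design_preset))
  if (!is.null(config$conditions)) {
    cond <- as.data.frame(config$conditions)
    return(experiment_design(
      cond, horizon = config$horizon %||% 30,
      n_replicates = config$n_replicates %||% 3,
      n_duplicates = config$n_duplicates %||% 2,
      read_interval = config$read_interval %||% 0.5,
      residual_sigma = config$residual_sigma %||% 0.01))
  }
  stop("configuration is invalid:\n  - provide 'design_preset' or ",
       "'conditions'", call. = FALSE)
}

config_params <- function(config) {
  if (!is.null(config$params_file)) read_parameter_set(config$params_file)
  else reference_parameters()
}

write_manifest <- function(out_dir, command, config, seed, files) {
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(command = command,
                   config_md5 = unname(tools::md5sum(tmp)),
                   package_version =
                     as.character(utils::packageVersion("allocamp")),
                   seed = seed, outputs = files)
  unlink(tmp)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a pipeline stage
#'
#' A configuration-driven front end binding the simulation, lag,
#' uncertainty, probe-dependence, synthetic-data and calibration stages
#' together. Each run writes its CSV/JSON artifacts plus a `manifest.json`
#' (config hash, package version, seed) into `config$out_dir`, enabling
#' exact re-runs. Stochastic commands (`synth`, `band`) require an explicit
#' seed; schema violations raise a validation report listing every failing
#' field.
#'
#' @param command One of `"simulate"`, `"lag"`, `"band"`, `"probe"`,
#'   `"synth"`, `"calibrate"`.
#' @param config Named list, or path to a JSON file holding one. Common
#'   fields: `out_dir`, `params_file`, `design_preset` or `conditions` (+
#'   `horizon`), `seed`. Command-specific fields: `traces` and `control`
#'   (lag), `n_draws`/`residual_sigma`/`level` (band), `agonists` (probe),
#'   `dataset` (calibrate), `tolerance` (lag/probe).
#' @return Invisibly, the character vector of files written.
#' @export
run_pipeline <- function(command = c("simulate", "lag", "band", "probe",
                                     "synth", "calibrate"),
                         config) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config))
    stop("config must be a named list or a JSON file path", call. = FALSE)
  validate_config(config, "out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(
    command,
    simulate = pipeline_simulate(config),
    lag = pipeline_lag(config),
    band = pipeline_band(config),
    probe = pipeline_probe(config),
    synth = pipeline_synth(config),
    calibrate = pipeline_calibrate(config))
  manifest <- write_manifest(config$out_dir, command, config,
                             config$seed %||% NA, files)
  invisible(c(files, manifest))
}

pipeline_simulate <- function(config) {
  design <- config_design(config)
  p <- config_params(config)
  lib <- agonist_library()
  cond <- design$conditions[order(design$conditions$condition), ]
  traces <- lapply(seq_len(nrow(cond)), function(i) {
    row <- cond[i, ]
    observe_trace(simulate_timecourse(condition_params(row$agonist, p, lib),
                                      condition_schedule(row, design),
                                      grid_step = design$read_interval),
                  condition = row$condition)
  })
  path <- file.path(config$out_dir, "traces.csv")
  write_traces(traces, path)
  path
}

pipeline_lag <- function(config) {
  validate_config(config, c("traces", "control"),
                  numeric_fields = c("tolerance", "t_ORG"))
  traces <- read_traces(config$traces)
  if (!config$control %in% names(traces))
    stop("control condition '", config$control, "' not found in traces",
         call. = FALSE)
  tol <- config$tolerance %||% 0.01
  t_ORG <- config$t_ORG %||% 0
  ctrl <- traces[[config$control]]
  results <- list()
  for (cn in setdiff(names(traces), config$control)) {
    tr <- traces[[cn]]
    results[[paste0(cn, "/model")]] <-
      model_lag(tr, ctrl, tolerance = tol, t_ORG = t_ORG)
    fit <- fit_plateau_one_phase(tr$times, tr$values - ctrl$values)
    results[[paste0(cn, "/experimental")]] <- if (fit$converged)
      experimental_lag(fit, tolerance = tol, t_ORG = t_ORG)
    else lag_result(NA, t_ORG, tol, "experimental", separated = FALSE)
  }
  path <- file.path(config$out_dir, "lag_table.csv")
  write_lag_table(results, path)
  path
}

pipeline_band <- function(config) {
  validate_config(config, c("seed", "A_uM", "B_uM"),
                  numeric_fields = c("seed", "n_draws", "A_uM", "B_uM",
                                     "residual_sigma", "level"))
  p <- config_params(config)
  spec <- if (!is.null(config$cov_csv))
    read_covariance_spec(config$cov_csv, config$cov_sidecar)
  else demo_covariance_spec(p)
  n <- config$n_draws %||% 200
  draws <- sample_parameters(spec, n, seed = config$seed, base = p)
  sched <- standard_schedule(config$A_uM, config$B_uM,
                             t_B = config$t_B %||% 0,
                             horizon = config$horizon %||% 30)
  band <- prediction_band(draws, sched, level = config$level %||% 0.95,
                          residual_sigma = config$residual_sigma %||% 0.01,
                          seed = config$seed + 1L)
  path <- file.path(config$out_dir, "prediction_band.csv")
  utils::write.csv(data.frame(time_min = band$times, lower = band$lower,
                              median = band$median, upper = band$upper),
                   path, row.names = FALSE)
  path
}

pipeline_probe <- function(config) {
  validate_config(config, "agonists",
                  numeric_fields = c("A_uM", "B_uM", "tolerance"))
  sched <- standard_schedule(config$A_uM %||% 1, config$B_uM %||% 1,
                             horizon = config$horizon %||% 30)
  res <- compare_profiles(unlist(config$agonists), sched,
                          tolerance = config$tolerance %||% 0.01)
  path <- file.path(config$out_dir, "probe_comparison.csv")
  utils::write.csv(res, path, row.names = FALSE)
  path
}

pipeline_synth <- function(config) {
  validate_config(config, "seed", numeric_fields = "seed")
  design <- config_design(config)
  ds <- generate_dataset(design, config_params(config), seed = config$seed)
  path <- file.path(config$out_dir, "dataset.csv")
  write_dataset(ds, path)
  path
}

pipeline_calibrate <- function(config) {
  validate_config(config, "dataset")
  design <- config_design(config)
  df <- read_dataset(config$dataset)
  ds <- structure(df, class = c("plate_dataset", "data.frame"),
                  design = design)
  means <- dataset_means(ds)
  with_b <- design$conditions$condition[design$conditions$B_uM > 0]
  targets <- means[names(means) %in% with_b]
  if (!length(targets))
    stop("no modulator-containing conditions found to calibrate against",
         call. = FALSE)
  grid <- if (!is.null(config$grid)) unlist(config$grid) else
    10^seq(log10(0.005), log10(5), length.out = 21)
  cal <- calibrate_kon3(targets, candidate_grid = grid,
                        p = config_params(config))
  path <- file.path(config$out_dir, "kon3_calibration.json")
  jsonlite::write_json(list(kon3 = cal$kon3, grid = cal$grid,
                            loss = cal$loss),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}
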