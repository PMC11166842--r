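#' Multivariate-normal specification of parameter uncertainty
#'
#' Describes the joint distribution of parameter estimates on their
#' estimation scale: `"linear"` parameters are sampled directly, `"log"`
#' parameters are sampled as natural logs and exponentiated back. Labels are
#' dotted parameter paths (see [param_get()]).
#'
#' @param mean Named numeric vector of means on the estimation scale.
#' @param cov Symmetric positive semi-definite covariance matrix (same
#'   order as `mean`).
#' @param scale_map Character vector (`"linear"`/`"log"`) per parameter;
#'   a single value is recycled.
#' @return A `covariance_spec`.
#' @export
covariance_spec <- function(mean, cov, scale_map = "log") {
  labels <- names(mean)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("mean must be a fully named vector of parameter paths",
         call. = FALSE)
  if (anyDuplicated(labels))
    stop("parameter labels must be unique", call. = FALSE)
  labels <- vapply(labels, resolve_param_path, "")
  names(mean) <- labels
  cov <- as.matrix(cov)
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean))
    stop("cov must be a ", length(mean), " x ", length(mean), " matrix",
         call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-10)
    stop("cov must be symmetric", call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("cov is not positive semi-definite (eigenvalue ",
         signif(min(ev), 4), ")", call. = FALSE)
  scale_map <- rep_len(scale_map, length(mean))
  if (!all(scale_map %in% c("linear", "log")))
    stop("scale_map entries must be 'linear' or 'log'", call. = FALSE)
  names(scale_map) <- labels
  structure(list(mean = mean, cov = cov, scale_map = scale_map,
                 labels = labels),
            class = "covariance_spec")
}

#' Shipped synthetic demonstration covariance
#'
#' No variance-covariance matrix of the original parameter estimates is
#' available, so this constructor builds a clearly synthetic stand-in for
#' demonstrating the uncertainty pipeline: independent log-normal uncertainty on a default set
#' of kinetic rates with coefficients of variation between 10 and 30%.
#'
#' @param p Base `parameter_set` supplying the central values.
#' @param cvs Named numeric vector of coefficients of variation; names are
#'   parameter paths. Defaults cover internalisation, modulator binding and
#'   cAMP turnover rates.
#' @return A `covariance_spec` on the log scale.
#' @export
demo_covariance_spec <- function(p = reference_parameters(),
                                 cvs = c(agonist.k_int = 0.15,
                                         allosteric.kon3 = 0.2,
                                         allosteric.koff3 = 0.3,
                                         system.k_out = 0.1)) {
  labels <- vapply(names(cvs), resolve_param_path, "")
  vals <- vapply(labels, function(l) param_get(p, l), 0)
  if (any(vals <= 0))
    stop("demo covariance requires strictly positive central values",
         call. = FALSE)
  mu <- log(vals)
  names(mu) <- labels
  sd_log <- sqrt(log(1 + cvs^2))
  covariance_spec(mu, diag(sd_log^2, nrow = length(mu)), scale_map = "log")
}

#' Read a covariance specification from CSV (+ JSON sidecar)
#'
#' @param cov_csv Square CSV with labelled header row and first column.
#' @param sidecar_json JSON file with fields `mean` (named) and `scale_map`
#'   (named, `"linear"`/`"log"`).
#' @return A `covariance_spec`.
#' @export
read_covariance_spec <- function(cov_csv, sidecar_json) {
  m <- as.matrix(utils::read.csv(cov_csv, row.names = 1, check.names = FALSE))
  if (!identical(rownames(m), colnames(m)))
    stop("covariance CSV row and column labels differ", call. = FALSE)
  side <- jsonlite::read_json(sidecar_json, simplifyVector = TRUE)
  if (is.null(side$mean) || is.null(names(side$mean)))
    stop("sidecar JSON must provide a named 'mean'", call. = FALSE)
  mean <- unlist(side$mean)[rownames(m)]
  scale_map <- if (!is.null(side$scale_map))
    unlist(side$scale_map)[rownames(m)] else "log"
  covariance_spec(mean, m, scale_map = unname(scale_map))
}

#' Sample parameter sets from a covariance specification
#'
#' Draws independent multivariate-normal vectors on the estimation scale,
#' back-transforms per the scale map and injects them into the base
#' parameter set. Draws yielding invalid parameters (e.g. negative rates on
#' the linear scale) are rejected and redrawn; the rejection count is
#' attached as attribute `"n_rejected"`.
#'
#' @param spec A `covariance_spec`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed (all randomness is seeded).
#' @param base Base `parameter_set` receiving the sampled fields.
#' @return List of `n` `parameter_set`s.
#' @export
sample_parameters <- function(spec, n, seed, base = reference_parameters()) {
  stopifnot(inherits(spec, "covariance_spec"), n >= 1)
  set.seed(seed)
  out <- vector("list", n)
  rejected <- 0L
  filled <- 0L
  guard <- 0L
  while (filled < n) {
    guard <- guard + 1L
    if (guard > 1000L)
      stop("too many rejected draws; check the covariance specification",
           call. = FALSE)
    need <- n - filled
    draws <- MASS::mvrnorm(need, mu = spec$mean, Sigma = spec$cov)
    if (need == 1) draws <- matrix(draws, nrow = 1,
                                   dimnames = list(NULL, spec$labels))
    for (i in seq_len(need)) {
      v <- draws[i, ]
      islog <- spec$scale_map == "log"
      v[islog] <- exp(v[islog])
      ps <- tryCatch(param_set(base, as.list(v)), error = function(e) NULL)
      if (is.null(ps)) rejected <- rejected + 1L
      else {
        filled <- filled + 1L
        out[[filled]] <- ps
      }
    }
  }
  attr(out, "n_rejected") <- rejected
  out
}

#' Simulation-based prediction band
#'
#' Simulates the schedule under every parameter draw, adds independent
#' Gaussian residual error at each observation time, and returns pointwise
#' quantiles (2.5/50/97.5% at the default 0.95 level). Identical draws are
#' simulated once. Failed simulations are excluded and counted; the band is
#' flagged when more than 5% fail.
#'
#' @param p_draws List of `parameter_set`s (use >= 100 draws for a 0.95
#'   band).
#' @param schedule A `dose_schedule`.
#' @param level Coverage probability of the band (default 0.95).
#' @param residual_sigma Additive Gaussian residual SD on the observed scale.
#' @param seed Integer seed for the residual noise.
#' @param grid_step Simulation output step (min).
#' @param method Model form passed to [simulate_timecourse()].
#' @return A `prediction_band`: list with `times`, `lower`, `median`,
#'   `upper`, `level`, `n_draws`, `seed`, `n_failed`, `flagged`.
#' @export
prediction_band <- function(p_draws, schedule, level = 0.95,
                            residual_sigma = 0, seed = 1, grid_step = 0.5,
                            method = "reduced") {
  stopifnot(length(p_draws) >= 1,
            all(vapply(p_draws, inherits, TRUE, "parameter_set")))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  keys <- vapply(p_draws, function(p)
    paste(signif(unlist(as.list(p, flatten = TRUE)), 15), collapse = ","), "")
  cache <- new.env(parent = emptyenv())
  times <- NULL
  n_failed <- 0L
  rows <- vector("list", length(p_draws))
  for (i in seq_along(p_draws)) {
    key <- keys[i]
    if (is.null(cache[[key]])) {
      tr <- tryCatch(simulate_timecourse(p_draws[[i]], schedule,
                                         grid_step = grid_step,
                                         method = method),
                     error = function(e) NULL)
      cache[[key]] <- if (is.null(tr)) NA else tr$C
      if (!is.null(tr) && is.null(times)) times <- tr$time
    }
    rows[[i]] <- cache[[key]]
  }
  ok <- !vapply(rows, function(r) length(r) == 1 && is.na(r[1]), TRUE)
  n_failed <- sum(!ok)
  if (!any(ok)) stop("all simulations failed", call. = FALSE)
  m <- do.call(rbind, rows[ok])
  set.seed(seed)
  if (residual_sigma > 0)
    m <- m + matrix(stats::rnorm(length(m), sd = residual_sigma),
                    nrow = nrow(m))
  a <- (1 - level) / 2
  qs <- apply(m, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  structure(list(times = times, lower = qs[1, ], median = qs[2, ],
                 upper = qs[3, ], level = level, n_draws = length(p_draws),
                 seed = seed, n_failed = n_failed,
                 flagged = n_failed > 0.05 * length(p_draws)),
            class = "prediction_band")
}

#' @export
print.prediction_band <- function(x, ...) {
  cat(sprintf(
    "prediction band: level %.2f, %d draws (%d failed), t = %g..%g min\n",
    x$level, x$n_draws, x$n_failed, min(x$times), max(x$times)))
  invisible(x)
}

#' Fraction of observations inside a prediction band
#'
#' @param observations A single [camp_trace()], a list of them, or a long
#'   data frame with columns `condition`, `time_min`, `value`.
#' @param band A `prediction_band`; bounds are linearly interpolated at the
#'   observation times, which must lie within the band's time support.
#' @param threshold Overall inside-fraction required for the pass flag
#'   (default 0.90 for a nominal 0.95 band).
#' @return List with `per_condition` (named fractions), `overall`, `n`, and
#'   logical `pass`.
#' @export
coverage_report <- function(observations, band, threshold = 0.90) {
  stopifnot(inherits(band, "prediction_band"))
  if (inherits(observations, "camp_trace")) observations <- list(observations)
  if (is.data.frame(observations)) {
    need <- c("condition", "time_min", "value")
    if (!all(need %in% names(observations)))
      stop("observation data frame needs columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    df <- observations[, need]
  } else {
    if (!length(observations)) stop("no observations supplied", call. = FALSE)
    stopifnot(all(vapply(observations, inherits, TRUE, "camp_trace")))
    df <- do.call(rbind, lapply(observations, function(tr)
      data.frame(condition = tr$condition, time_min = tr$times,
                 value = tr$values)))
  }
  if (!nrow(df)) stop("no observations supplied", call. = FALSE)
  if (min(df$time_min) < min(band$times) - 1e-9 ||
      max(df$time_min) > max(band$times) + 1e-9)
    stop("observation times fall outside the band's time support",
         call. = FALSE)
  lo <- stats::approx(band$times, band$lower, xout = df$time_min)$y
  hi <- stats::approx(band$times, band$upper, xout = df$time_min)$y
  inside <- df$value >= lo & df$value <= hi
  per <- tapply(inside, df$condition, mean)
  overall <- mean(inside)
  list(per_condition = per, overall = overall, n = nrow(df),
       pass = overall >= threshold)
}
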