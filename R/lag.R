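#' Kinetic-lag result
#'
#' @param T_S Separation time (min), or `NA` when the curves never separate.
#' @param t_ORG Modulator addition time (min).
#' @param tolerance Separation threshold (response units).
#' @param method `"model"` or `"experimental"`.
#' @param separated Logical; `FALSE` when the threshold is never exceeded
#'   within the horizon.
#' @param fit Optional `association_fit` that produced an experimental lag.
#' @return A `lag_result` with `T_d = T_S - t_ORG`.
#' @export
lag_result <- function(T_S, t_ORG, tolerance, method, separated,
                       fit = NULL) {
  T_d <- if (separated) T_S - t_ORG else NA_real_
  if (separated && T_d < 0)
    stop("separation occurs before the modulator addition time (T_S = ",
         signif(T_S, 4), " < t_ORG = ", t_ORG, ")", call. = FALSE)
  structure(list(T_S = if (separated) T_S else NA_real_, T_d = T_d,
                 t_ORG = t_ORG, tolerance = tolerance, method = method,
                 separated = separated, fit = fit),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  if (x$separated)
    cat(sprintf("kinetic lag (%s): T_S = %.3f min, T_d = %.3f min (tolerance %g)\n",
                x$method, x$T_S, x$T_d, x$tolerance))
  else
    cat(sprintf("kinetic lag (%s): curves never separate (tolerance %g)\n",
                x$method, x$tolerance))
  invisible(x)
}

#' Model-predicted kinetic lag
#'
#' Subtracts the modulator-free reference curve pointwise from the
#' modulator-containing curve and records the first time the signed
#' difference exceeds `tolerance` (linearly interpolated between the
#' bracketing grid points). A modulator trace that falls below the reference
#' never triggers separation. `T_d = T_S - t_ORG`.
#'
#' @param trace_with_B,trace_without_B [camp_trace()]s on an identical time
#'   grid.
#' @param tolerance Separation threshold on the response scale (default
#'   0.01).
#' @param t_ORG Modulator addition time (min, default 0).
#' @return A [lag_result()] with `method = "model"`.
#' @export
model_lag <- function(trace_with_B, trace_without_B, tolerance = 0.01,
                      t_ORG = 0) {
  stopifnot(inherits(trace_with_B, "camp_trace"),
            inherits(trace_without_B, "camp_trace"))
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  if (length(trace_with_B$times) != length(trace_without_B$times) ||
      any(abs(trace_with_B$times - trace_without_B$times) > 1e-9))
    stop("traces must share an identical time grid", call. = FALSE)
  t <- trace_with_B$times
  d <- trace_with_B$values - trace_without_B$values
  over <- which(d > tolerance & t >= t_ORG)
  if (!length(over))
    return(lag_result(NA, t_ORG, tolerance, "model", separated = FALSE))
  i <- over[1]
  T_S <- if (i == 1) t[1] else
    t[i - 1] + (tolerance - d[i - 1]) / (d[i] - d[i - 1]) * (t[i] - t[i - 1])
  T_S <- max(T_S, t_ORG)
  lag_result(T_S, t_ORG, tolerance, "model", separated = TRUE)
}

#' Plateau-followed-by-one-phase-association fit
#'
#' Least-squares fit of the piecewise kinetic model used for empirical lag
#' estimation: the response equals `Y0` up to the onset time `X0` and
#' `Y0 + (plateau - Y0) * (1 - exp(-K * (t - X0)))` afterwards. The fit is
#' multi-started over a grid of candidate onset times (observation times
#' between the 5th and 95th percentile); the candidate with the lowest
#' residual sum of squares wins, ties broken toward the earliest onset.
#'
#' @param times Observation times (min), increasing, at least 6 points.
#' @param values Response values (typically a modulator condition after
#'   subtracting the mean agonist+forskolin curve).
#' @param start Optional named list of starting values
#'   (`Y0`, `X0`, `plateau`, `K`).
#' @return An `association_fit` with elements `Y0`, `X0`, `plateau`, `K`,
#'   `rss`, `converged` and `degenerate`.
#' @export
fit_plateau_one_phase <- function(times, values, start = NULL) {
  if (length(times) < 6)
    stop("at least 6 points are required", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(values) != length(times))
    stop("times and values must have the same length", call. = FALSE)
  if (stats::sd(values) < 1e-12) {
    return(structure(list(Y0 = values[1], X0 = times[1],
                          plateau = values[1], K = NA_real_,
                          rss = 0, converged = FALSE, degenerate = TRUE),
                     class = "association_fit"))
  }
  df <- data.frame(t = times, y = values)
  one_fit <- function(st) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ ifelse(t < X0, Y0, Y0 + (plateau - Y0) * (1 - exp(-K * (t - X0)))),
        data = df, start = st,
        lower = c(Y0 = -Inf, X0 = min(times), plateau = -Inf, K = 1e-6),
        upper = c(Y0 = Inf, X0 = max(times), plateau = Inf, K = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- stats::coef(fit)
      list(coef = cf, rss = sum(stats::resid(fit)^2), ok = TRUE)
    }, error = function(e) list(ok = FALSE))
  }
  starts <- list()
  if (!is.null(start)) starts <- list(start[c("Y0", "X0", "plateau", "K")])
  x0_grid <- unique(stats::quantile(times, probs = seq(0.05, 0.95, by = 0.1),
                                    names = FALSE, type = 7))
  nearly <- function(x) times[which.min(abs(times - x))]
  y_early <- mean(values[seq_len(max(3, length(values) %/% 10))])
  y_late <- mean(values[seq(length(values) - max(3, length(values) %/% 10),
                            length(values))])
  for (x0 in x0_grid)
    starts <- c(starts, list(list(Y0 = y_early, X0 = nearly(x0),
                                  plateau = y_late, K = 0.2)))
  best <- NULL
  for (st in starts) {
    r <- one_fit(st)
    if (!r$ok) next
    if (is.null(best) || r$rss < best$rss - 1e-12 ||
        (abs(r$rss - best$rss) <= 1e-12 && r$coef[["X0"]] < best$coef[["X0"]]))
      best <- r
  }
  if (is.null(best))
    return(structure(list(Y0 = NA_real_, X0 = NA_real_, plateau = NA_real_,
                          K = NA_real_, rss = NA_real_, converged = FALSE,
                          degenerate = FALSE),
                     class = "association_fit"))
  cf <- best$coef
  structure(list(Y0 = unname(cf["Y0"]), X0 = unname(cf["X0"]),
                 plateau = unname(cf["plateau"]), K = unname(cf["K"]),
                 rss = best$rss, converged = TRUE, degenerate = FALSE),
            class = "association_fit")
}

#' Evaluate an association fit
#' @param object An `association_fit`.
#' @param times Times (min) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Fitted values.
#' @export
predict.association_fit <- function(object, times, ...) {
  with(object, ifelse(times < X0, Y0,
                      Y0 + (plateau - Y0) * (1 - exp(-K * (times - X0)))))
}

#' @export
print.association_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "one-phase association fit: Y0 = %.4g, X0 = %.4g min, plateau = %.4g, K = %.4g /min (rss %.3g)\n",
      x$Y0, x$X0, x$plateau, x$K, x$rss))
  else cat("one-phase association fit: not converged",
           if (isTRUE(x$degenerate)) "(degenerate, flat data)" else "", "\n")
  invisible(x)
}

#' Experiment-style kinetic lag from an association fit
#'
#' Solves, in closed form, for the earliest time at which the fitted curve
#' exceeds its initial plateau by `tolerance`:
#' `T_S = X0 + log((plateau - Y0) / (plateau - Y0 - tolerance)) / K`.
#' Input data are assumed pre-normalised by subtracting the mean
#' agonist+forskolin reference curve (so `Y0` is near zero).
#'
#' @param fit A converged `association_fit`.
#' @param tolerance Separation threshold (default 0.01).
#' @param t_ORG Modulator addition time (min).
#' @return A [lag_result()] with `method = "experimental"`;
#'   `separated = FALSE` when the fitted rise `plateau - Y0` never exceeds
#'   the tolerance.
#' @export
experimental_lag <- function(fit, tolerance = 0.01, t_ORG = 0) {
  stopifnot(inherits(fit, "association_fit"))
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  if (!isTRUE(fit$converged))
    stop("association fit did not converge; no lag can be derived",
         call. = FALSE)
  rise <- fit$plateau - fit$Y0
  if (rise <= tolerance)
    return(lag_result(NA, t_ORG, tolerance, "experimental",
                      separated = FALSE, fit = fit))
  T_S <- fit$X0 + log(rise / (rise - tolerance)) / fit$K
  lag_result(T_S, t_ORG, tolerance, "experimental", separated = TRUE,
             fit = fit)
}

#' Collect lag results into an exportable table
#'
#' @param results Named list of `lag_result`s (names are condition labels).
#' @return Data frame with columns condition, method, tolerance, T_S, T_d,
#'   separated.
#' @export
lag_table <- function(results) {
  stopifnot(all(vapply(results, inherits, TRUE, "lag_result")))
  nm <- names(results) %||% as.character(seq_along(results))
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(condition = nm[i], method = r$method,
               tolerance = r$tolerance, T_S = r$T_S, T_d = r$T_d,
               separated = r$separated)
  }))
}
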