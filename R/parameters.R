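#' Ligand-specific (orthosteric agonist) parameters
#'
#' Bundles the three agonist-specific constants of the unified CB1 model
#' (equilibrium affinity, internalisation rate, intrinsic efficacy) together
#' with the agonist association rate used to resolve binding kinetics.
#'
#' @param pKd Negative log10 of the equilibrium dissociation constant (molar).
#' @param k_int Internalisation rate of agonist-bound receptor (1/min).
#' @param log10_eps log10 of the intrinsic efficacy of the agonist-bound
#'   receptor in the inhibition signal (dimensionless).
#' @param kon_A Association rate of agonist to free receptor (1/uM/min).
#'
#' @return An object of class `ligand_params`.
#' @export
ligand_params <- function(pKd, k_int, log10_eps, kon_A = 10) {
  stopifnot(is.numeric(pKd), is.numeric(k_int), is.numeric(log10_eps),
            is.numeric(kon_A))
  if (!is.finite(pKd) || pKd <= 4 || pKd >= 12)
    stop("pKd must lie in (4, 12), got ", pKd, call. = FALSE)
  if (!is.finite(k_int) || k_int < 0)
    stop("k_int must be a non-negative rate (1/min), got ", k_int,
         call. = FALSE)
  if (!is.finite(log10_eps))
    stop("log10_eps must be finite", call. = FALSE)
  if (!is.finite(kon_A) || kon_A <= 0)
    stop("kon_A must be a positive rate (1/uM/min), got ", kon_A,
         call. = FALSE)
  structure(list(pKd = pKd, k_int = k_int, log10_eps = log10_eps,
                 kon_A = kon_A),
            class = "ligand_params")
}

#' Allosteric-modulator and interaction parameters
#'
#' Rates governing modulator binding to free and agonist-occupied receptor,
#' the transition between the ternary transitional state (which internalises
#' but cannot signal) and the fully inactive ternary state, and the
#' internalisation rate of the transitional state.
#'
#' @param kon3 Association rate of modulator to agonist-occupied receptor
#'   (1/uM/min).
#' @param koff3 Dissociation rate of modulator from the transitional ternary
#'   state (1/min).
#' @param kon2 Association rate of modulator to free receptor (1/uM/min).
#' @param Kd_B Dissociation constant of modulator at free receptor (uM).
#' @param k_TI Forward transition rate, transitional -> inactive ternary
#'   state (1/min); only exercised by the full (non-reduced) model.
#' @param K_TI_eq Quasi-equilibrium ratio inactive/transitional ternary
#'   state (dimensionless).
#' @param k_int_T Internalisation rate of the transitional ternary state
#'   (1/min). Defaults to the agonist `k_int` when built through
#'   [reference_parameters()].
#'
#' @return An object of class `allosteric_params`.
#' @export
allosteric_params <- function(kon3 = 0.528, koff3, kon2, Kd_B, k_TI,
                              K_TI_eq, k_int_T) {
  vals <- list(kon3 = kon3, koff3 = koff3, kon2 = kon2, Kd_B = Kd_B,
               k_TI = k_TI, K_TI_eq = K_TI_eq, k_int_T = k_int_T)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || !is.finite(v) || v < 0)
      stop(nm, " must be a non-negative finite number, got ", v,
           call. = FALSE)
  }
  structure(vals, class = "allosteric_params")
}

#' System-level parameters
#'
#' Constants of the cellular context: receptor normalisation, constitutive
#' efficacy, the EMAX coupling of the inhibition signal to cAMP production,
#' and forskolin-driven cAMP turnover. cAMP is normalised so that the
#' receptor-free forskolin steady state `k_in / k_out` equals 1.
#'
#' @param R0 Initial total surface receptor; the normalisation unit (= 1).
#' @param k_syn_R Receptor synthesis rate (R0 units/min).
#' @param eps_R Efficacy of constitutively active receptor (= 1).
#' @param I50 Half-maximal inhibition signal (R0-equivalents).
#' @param Imax Maximal fractional inhibition of cAMP production (<= 1).
#' @param k_in cAMP production drive under 5 uM forskolin (response/min).
#' @param k_out cAMP turnover rate (1/min).
#'
#' @return An object of class `system_params`.
#' @export
system_params <- function(R0 = 1, k_syn_R = 0, eps_R = 1, I50, Imax = 1,
                          k_in, k_out) {
  if (!isTRUE(all.equal(R0, 1)))
    stop("R0 is the normalisation unit and must equal 1", call. = FALSE)
  if (!isTRUE(all.equal(eps_R, 1)))
    stop("eps_R (constitutive efficacy) must equal 1", call. = FALSE)
  if (!is.finite(Imax) || Imax <= 0 || Imax > 1)
    stop("Imax must lie in (0, 1]", call. = FALSE)
  for (nm in c("k_syn_R", "I50", "k_in", "k_out")) {
    v <- get(nm)
    if (!is.numeric(v) || !is.finite(v) || v < 0)
      stop(nm, " must be a non-negative finite number, got ", v,
           call. = FALSE)
  }
  if (k_out <= 0) stop("k_out must be positive", call. = FALSE)
  structure(list(R0 = R0, k_syn_R = k_syn_R, eps_R = eps_R, I50 = I50,
                 Imax = Imax, k_in = k_in, k_out = k_out),
            class = "system_params")
}

#' Full model parameterisation
#'
#' @param agonist A [ligand_params()] object.
#' @param allosteric An [allosteric_params()] object.
#' @param system A [system_params()] object.
#' @param provenance Named character vector tagging fields as one of
#'   `"printed"`, `"derived"`, `"calibrated"`; names use dotted paths such
#'   as `"agonist.pKd"`.
#'
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(agonist, allosteric, system,
                          provenance = character()) {
  stopifnot(inherits(agonist, "ligand_params"),
            inherits(allosteric, "allosteric_params"),
            inherits(system, "system_params"))
  if (length(provenance)) {
    bad <- setdiff(unique(provenance), c("printed", "derived", "calibrated"))
    if (length(bad))
      stop("unknown provenance tag(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  structure(list(agonist = agonist, allosteric = allosteric,
                 system = system, provenance = provenance),
            class = "parameter_set")
}

param_field_paths <- function() {
  c(paste0("agonist.", c("pKd", "k_int", "log10_eps", "kon_A")),
    paste0("allosteric.",
           c("kon3", "koff3", "kon2", "Kd_B", "k_TI", "K_TI_eq", "k_int_T")),
    paste0("system.",
           c("R0", "k_syn_R", "eps_R", "I50", "Imax", "k_in", "k_out")))
}

#' Look up a parameter by dotted path
#' @param p A `parameter_set`.
#' @param path Dotted path such as `"allosteric.kon3"`; bare field names are
#'   resolved when unambiguous.
#' @return The numeric value.
#' @export
param_get <- function(p, path) {
  path <- resolve_param_path(path)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  p[[parts[1]]][[parts[2]]]
}

#' Replace parameters by dotted path
#' @param p A `parameter_set`.
#' @param values Named list/vector of replacements; names as in
#'   [param_get()]. Replaced fields are re-tagged `"calibrated"` unless a
#'   `provenance` attribute accompanies the call.
#' @param provenance Optional tag applied to the replaced fields.
#' @return The modified `parameter_set` (re-validated).
#' @export
param_set <- function(p, values, provenance = "calibrated") {
  stopifnot(inherits(p, "parameter_set"))
  if (!length(values)) return(p)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("all override values must be named", call. = FALSE)
  raw <- as.list(p, flatten = TRUE)
  prov <- p$provenance
  for (nm in names(values)) {
    path <- resolve_param_path(nm)
    v <- values[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("override for '", nm, "' must be a single finite number",
           call. = FALSE)
    raw[[path]] <- v
    prov[path] <- provenance
  }
  rebuild_parameter_set(raw, prov)
}

resolve_param_path <- function(path) {
  all <- param_field_paths()
  if (path %in% all) return(path)
  hit <- all[sub("^[a-z]+\\.", "", all) == path]
  if (length(hit) == 1) return(hit)
  if (length(hit) > 1)
    stop("parameter name '", path, "' is ambiguous: ",
         paste(hit, collapse = ", "), call. = FALSE)
  stop("unknown parameter '", path, "'; known fields: ",
       paste(all, collapse = ", "), call. = FALSE)
}

rebuild_parameter_set <- function(raw, prov) {
  pick <- function(block) {
    v <- raw[grep(paste0("^", block, "\\."), names(raw))]
    names(v) <- sub("^[a-z]+\\.", "", names(v))
    v
  }
  parameter_set(
    agonist = do.call(ligand_params, pick("agonist")),
    allosteric = do.call(allosteric_params, pick("allosteric")),
    system = do.call(system_params, pick("system")),
    provenance = prov
  )
}

#' @export
as.list.parameter_set <- function(x, flatten = FALSE, ...) {
  if (!flatten) return(unclass(x))
  out <- list()
  for (block in c("agonist", "allosteric", "system"))
    for (nm in names(x[[block]]))
      out[[paste0(block, ".", nm)]] <- x[[block]][[nm]]
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("CB1 allosteric model parameter set\n")
  flat <- as.list(x, flatten = TRUE)
  prov <- x$provenance
  for (nm in names(flat)) {
    tag <- if (nm %in% names(prov)) prov[[nm]] else "?"
    cat(sprintf("  %-22s %-12g [%s]\n", nm, flat[[nm]], tag))
  }
  invisible(x)
}

#' Half-maximal inhibition constant from a stated efficacy/response pair
#'
#' Recovers the EMAX half-maximal constant I50 by root finding: given that an
#' agonist-bound receptor fraction `AR` with intrinsic efficacy `eps`
#' produces fractional inhibition `inhibition` (constitutive contribution
#' ignored), solve `Imax * I / (I50 + I) = inhibition` with `I = eps * AR`.
#'
#' @param eps Intrinsic efficacy of the agonist-bound receptor.
#' @param AR Agonist-bound receptor fraction of R0.
#' @param inhibition Fractional inhibition observed at that occupancy.
#' @param Imax Maximal fractional inhibition (default 1).
#' @return The I50 (R0-equivalents) solving the EMAX relation.
#' @export
#' @examples
#' derive_i50(eps = 45.7, AR = 0.1, inhibition = 0.82)
derive_i50 <- function(eps, AR, inhibition, Imax = 1) {
  stopifnot(eps > 0, AR > 0, inhibition > 0, inhibition < Imax)
  I <- eps * AR
  f <- function(i50) Imax * I / (i50 + I) - inhibition
  stats::uniroot(f, interval = c(1e-8, 1e6), tol = 1e-12)$root
}

#' Reference parameter set (CP55940 + ORG27569)
#'
#' The shipped parameterisation of the unified CB1 model for the reference
#' agonist CP55940 with the allosteric modulator ORG27569. Printed constants
#' (pKd = 8.6, k_int = 0.15/min, log10 efficacy = 1.66, kon3 =
#' 0.528/uM/min) are tagged `"printed"`; I50 is derived by root finding from
#' the efficacy/inhibition normalisation (see [derive_i50()]); all remaining
#' rates are shipped calibrated defaults regenerated by
#' `scripts/calibrate_defaults.R` and tagged `"calibrated"`. The defaults are
#' read from the packaged file `params/reference_cp_org.json`, the single
#' source of truth.
#'
#' @param ... Named overrides; names are dotted paths or unambiguous bare
#'   field names (e.g. `kon3 = 0.05`). Overridden fields are re-tagged
#'   `"calibrated"`.
#' @return A `parameter_set`.
#' @export
#' @examples
#' p <- reference_parameters()
#' p$agonist$pKd
#' p2 <- reference_parameters(kon3 = 0.05)
#' p2$allosteric$kon3
reference_parameters <- function(...) {
  overrides <- list(...)
  if (length(overrides) == 1 && is.null(names(overrides)) &&
      is.list(overrides[[1]]))
    overrides <- overrides[[1]]
  path <- system.file("extdata", "params", "reference_cp_org.json",
                      package = "allocamp", mustWork = TRUE)
  p <- read_parameter_set(path)
  if (length(overrides)) p <- param_set(p, overrides)
  p
}

#' Derived quantities of a parameter set
#'
#' @param p A `parameter_set`.
#' @return Named list: `Kd_uM` (agonist dissociation constant,
#'   `10^(6 - pKd)`), `eps` (intrinsic efficacy `10^log10_eps`), `koff_A`
#'   (agonist dissociation rate `kon_A * Kd`), and the modulator-at-free-
#'   receptor dissociation quantities `Kd_B` and `koff2 = kon2 * Kd_B`.
#' @export
#' @examples
#' derived_quantities(reference_parameters())$eps  # 45.7 (3 s.f.)
derived_quantities <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  Kd <- 10^(6 - p$agonist$pKd)
  list(Kd_uM = Kd,
       eps = 10^p$agonist$log10_eps,
       koff_A = p$agonist$kon_A * Kd,
       Kd_B = p$allosteric$Kd_B,
       koff2 = p$allosteric$kon2 * p$allosteric$Kd_B)
}

## ---- JSON serialisation -------------------------------------------------

param_units <- function() {
  c(agonist.pKd = "-log10(M)", agonist.k_int = "1/min",
    agonist.log10_eps = "log10(dimensionless)", agonist.kon_A = "1/uM/min",
    allosteric.kon3 = "1/uM/min", allosteric.koff3 = "1/min",
    allosteric.kon2 = "1/uM/min", allosteric.Kd_B = "uM",
    allosteric.k_TI = "1/min", allosteric.K_TI_eq = "dimensionless",
    allosteric.k_int_T = "1/min",
    system.R0 = "R0 (dimensionless)", system.k_syn_R = "R0/min",
    system.eps_R = "dimensionless", system.I50 = "R0-equivalents",
    system.Imax = "dimensionless", system.k_in = "response/min",
    system.k_out = "1/min")
}

#' Write a parameter set to JSON
#'
#' Serialises values with explicit unit strings and provenance tags; the
#' round trip through [read_parameter_set()] is lossless.
#'
#' @param p A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(p, path) {
  stopifnot(inherits(p, "parameter_set"))
  flat <- as.list(p, flatten = TRUE)
  units <- param_units()
  out <- list()
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    out[[parts[1]]][[parts[2]]] <- list(
      value = flat[[nm]], unit = unname(units[nm]),
      provenance = if (nm %in% names(p$provenance))
        unname(p$provenance[[nm]]) else "calibrated")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path A JSON file written by [write_parameter_set()] (or the shipped
#'   `params/reference_cp_org.json`).
#' @return A `parameter_set`.
#' @export
read_parameter_set <- function(path) {
  raw <- jsonlite::read_json(path)
  vals <- list()
  prov <- character()
  for (block in c("agonist", "allosteric", "system")) {
    if (is.null(raw[[block]]))
      stop("parameter file is missing block '", block, "': ", path,
           call. = FALSE)
    for (nm in names(raw[[block]])) {
      key <- paste0(block, ".", nm)
      vals[[key]] <- raw[[block]][[nm]]$value
      prov[key] <- raw[[block]][[nm]]$provenance %||% "calibrated"
    }
  }
  rebuild_parameter_set(vals, prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
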