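#' Combined inhibition signal
#'
#' The receptor-mediated inhibition signal driving cAMP suppression:
#' `I = eps_R * R + eps * AR`, where only the constitutively active free
#' receptor and the agonist-bound receptor signal; ternary species do not.
#'
#' @param state Named numeric state vector containing at least `R` and `AR`
#'   (fractions of R0).
#' @param p A `parameter_set`.
#' @return The inhibition signal (R0-equivalents).
#' @export
#' @examples
#' p <- reference_parameters()
#' inhibition_signal(c(R = 0, AR = 0.1), p)  # 4.57
inhibition_signal <- function(state, p) {
  stopifnot(inherits(p, "parameter_set"))
  eps <- 10^p$agonist$log10_eps
  unname(p$system$eps_R * state[["R"]] + eps * state[["AR"]])
}

#' Fractional inhibition of cAMP production (EMAX model)
#'
#' @param I Inhibition signal (R0-equivalents), non-negative.
#' @param p A `parameter_set` supplying `Imax` and `I50`.
#' @return Fraction of cAMP production suppressed, in `[0, Imax]`.
#' @export
#' @examples
#' p <- reference_parameters()
#' fractional_inhibition(4.57, p)  # ~0.82
fractional_inhibition <- function(I, p) {
  stopifnot(inherits(p, "parameter_set"))
  if (any(!is.finite(I)) || any(I < 0))
    stop("inhibition signal I must be finite and non-negative",
         call. = FALSE)
  p$system$Imax * I / (p$system$I50 + I)
}

## Names of the full and reduced state vectors. In the reduced model the
## free receptor is lumped with its modulator-bound form (U = R + RB,
## partitioned by the B/Kd_B equilibrium) and the two ternary states are
## lumped (W = ARB_T + ARB, partitioned by K_TI_eq).
full_state_names <- function()
  c("R", "AR", "ARB_T", "ARB", "RB", "R_lost", "C")
reduced_state_names <- function() c("U", "AR", "W", "R_lost", "C")

## Flatten a parameter_set into the numeric constants the RHS needs.
rhs_constants <- function(p) {
  d <- derived_quantities(p)
  list(kon_A = p$agonist$kon_A, koff_A = d$koff_A,
       k_int = p$agonist$k_int, eps = d$eps,
       kon3 = p$allosteric$kon3, koff3 = p$allosteric$koff3,
       kon2 = p$allosteric$kon2, koff2 = d$koff2,
       Kd_B = p$allosteric$Kd_B,
       k_TI = p$allosteric$k_TI, K_TI_eq = p$allosteric$K_TI_eq,
       k_int_T = p$allosteric$k_int_T,
       eps_R = p$system$eps_R, I50 = p$system$I50, Imax = p$system$Imax,
       k_in = p$system$k_in, k_out = p$system$k_out,
       k_syn_R = p$system$k_syn_R)
}

check_ligands <- function(ligands) {
  if (is.null(ligands$A) || is.null(ligands$B) || is.null(ligands$forskolin))
    stop("ligands must be a list with elements A, B (uM) and forskolin ",
         "(logical)", call. = FALSE)
  if (ligands$A < 0 || ligands$B < 0)
    stop("ligand concentrations must be non-negative", call. = FALSE)
  ligands
}

#' Mass-action right-hand side of the full model
#'
#' Full seven-state scheme: `A + R <-> AR`, `B + R <-> RB`,
#' `B + AR <-> ARB_T`, `ARB_T <-> ARB` (forward `k_TI`, backward
#' `k_TI / K_TI_eq`); `AR` and `ARB_T` internalise (flux collected in
#' `R_lost`); free receptor is synthesised at `k_syn_R`; cAMP follows
#' `dC/dt = k_in * (1 - fractional_inhibition(I)) - k_out * C` while
#' forskolin is present and `-k_out * C` otherwise.
#'
#' @param state Named numeric vector with entries
#'   `R, AR, ARB_T, ARB, RB, R_lost, C`.
#' @param t Time (minutes); the system is autonomous, `t` is accepted for
#'   integrator compatibility.
#' @param p A `parameter_set`.
#' @param ligands List with ambient concentrations `A`, `B` (uM) and logical
#'   `forskolin`.
#' @return Named list whose first element is the derivative vector
#'   (deSolve convention).
#' @export
full_rhs <- function(state, t = 0, p, ligands) {
  stopifnot(inherits(p, "parameter_set"))
  k <- rhs_constants(p)
  lg <- check_ligands(ligands)
  if (any(!is.finite(state)))
    stop("non-finite state passed to full_rhs", call. = FALSE)
  full_rhs_raw(t, state[full_state_names()], k, lg$A, lg$B,
               isTRUE(lg$forskolin) || (is.numeric(lg$forskolin) &&
                                          lg$forskolin > 0))
}

full_rhs_raw <- function(t, y, k, A, B, fsk) {
  R <- y[[1]]; AR <- y[[2]]; ARBT <- y[[3]]; ARB <- y[[4]]; RB <- y[[5]]
  C <- y[[7]]
  bindA <- k$kon_A * A * R - k$koff_A * AR
  bind2 <- k$kon2 * B * R - k$koff2 * RB
  bind3 <- k$kon3 * B * AR - k$koff3 * ARBT
  trans <- if (k$K_TI_eq > 0)
    k$k_TI * ARBT - (k$k_TI / k$K_TI_eq) * ARB else 0
  dR <- -bindA - bind2 + k$k_syn_R
  dAR <- bindA - bind3 - k$k_int * AR
  dARBT <- bind3 - trans - k$k_int_T * ARBT
  dARB <- trans
  dRB <- bind2
  dRl <- k$k_int * AR + k$k_int_T * ARBT
  I <- k$eps_R * R + k$eps * AR
  prod <- if (fsk) k$k_in * (1 - k$Imax * I / (k$I50 + I)) else 0
  dC <- prod - k$k_out * C
  list(c(dR, dAR, dARBT, dARB, dRB, dRl, dC))
}

#' Quasi-equilibrium (reduced) right-hand side
#'
#' The reduction assumes the inactive ternary state `ARB` and the
#' modulator-bound free receptor `RB` are in quasi-equilibrium with their
#' partners: the lumped pools are `U = R + RB` (partitioned by `B / Kd_B`)
#' and `W = ARB_T + ARB` (partitioned by `K_TI_eq`). With `B = 0` the
#' scheme reduces exactly to the two-species agonist-only model. The reduced
#' trajectories agree with [full_rhs()] in the fast-equilibration limit.
#'
#' @param state Named numeric vector with entries `U, AR, W, R_lost, C`.
#' @inheritParams full_rhs
#' @return Named list whose first element is the derivative vector.
#' @export
reduced_rhs <- function(state, t = 0, p, ligands) {
  stopifnot(inherits(p, "parameter_set"))
  k <- rhs_constants(p)
  lg <- check_ligands(ligands)
  if (any(!is.finite(state)))
    stop("non-finite state passed to reduced_rhs", call. = FALSE)
  reduced_rhs_raw(t, state[reduced_state_names()], k, lg$A, lg$B,
                  isTRUE(lg$forskolin) || (is.numeric(lg$forskolin) &&
                                             lg$forskolin > 0))
}

reduced_rhs_raw <- function(t, y, k, A, B, fsk) {
  U <- y[[1]]; AR <- y[[2]]; W <- y[[3]]; C <- y[[5]]
  R <- U / (1 + B / k$Kd_B)
  ARBT <- W / (1 + k$K_TI_eq)
  bindA <- k$kon_A * A * R - k$koff_A * AR
  bind3 <- k$kon3 * B * AR - k$koff3 * ARBT
  dU <- -bindA + k$k_syn_R
  dAR <- bindA - bind3 - k$k_int * AR
  dW <- bind3 - k$k_int_T * ARBT
  dRl <- k$k_int * AR + k$k_int_T * ARBT
  I <- k$eps_R * R + k$eps * AR
  prod <- if (fsk) k$k_in * (1 - k$Imax * I / (k$I50 + I)) else 0
  dC <- prod - k$k_out * C
  list(c(dU, dAR, dW, dRl, dC))
}

## Expand a reduced state matrix (columns U, AR, W, R_lost, C) into the full
## species set under the quasi-equilibrium partition at ambient B.
expand_reduced_states <- function(m, k, B) {
  fB <- 1 / (1 + B / k$Kd_B)
  fT <- 1 / (1 + k$K_TI_eq)
  data.frame(
    R = m[, "U"] * fB,
    AR = m[, "AR"],
    ARB_T = m[, "W"] * fT,
    ARB = m[, "W"] * (1 - fT),
    RB = m[, "U"] * (1 - fB),
    R_lost = m[, "R_lost"],
    C = m[, "C"]
  )
}
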