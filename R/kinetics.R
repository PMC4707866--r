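# Well-mixed fibrinolysis kinetics: reversible adsorption of tPA/PLG/PLS onto
# fibrin binding sites, Michaelis-Menten plasmin generation in the bound
# phase, fibrin lysis by bound plasmin, solubilization of bound species as
# their supporting fibrin dissolves, and antiplasmin inhibition of free
# plasmin. The free phase is a stirred plasma pool of `plasma_volume_ratio`
# clot volumes plus the clot pore fluid; the balance is solved for the pooled
# amount F_alpha = (V_r + eps) * C_alpha (with V_r = 0 this is the superficial
# concentration eps * C_alpha).

SPECIES <- c("tPA", "PLG", "PLS")

#' Net adsorption rate onto the fibrin surface
#'
#' A_alpha = k_ads * C_alpha * (theta_alpha - occupied_alpha)
#'         - k_rev * S_alpha, positive for net adsorption. `occupied` is the
#' total occupancy of the site class the species binds (for PLG/PLS the shared
#' class carries both).
#'
#' @param C free concentration (uM)
#' @param S bound concentration of the species itself (uM)
#' @param theta total binding-site concentration of its class (uM)
#' @param occupied total occupancy of that class (uM), >= S
#' @param p [kineticParams()]
#' @param species "tPA", "PLG" or "PLS"
#' @return net adsorption rate (uM/s)
#' @export
adsorptionRate <- function(C, S, theta, occupied, p, species) {
  species <- match.arg(species, SPECIES)
  if (any(C < 0) || any(S < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  if (any(occupied > theta * (1 + 1e-9)))
    stop("occupied sites exceed theta", call. = FALSE)
  p$k_ads[[species]] * C * pmax(theta - occupied, 0) - p$k_rev[[species]] * S
}

#' Plasmin generation rate on the fibrin surface
#'
#' Michaelis-Menten in the bound phase:
#' G_PLS = k2 * S_tPA * S_PLG / (K_M + S_PLG); bound plasminogen is consumed
#' at the same rate.
#'
#' @param S_tPA bound tPA (uM)
#' @param S_PLG bound plasminogen (uM)
#' @param p [kineticParams()]
#' @return generation rate (uM/s)
#' @export
plasminGenerationRate <- function(S_tPA, S_PLG, p) {
  if (any(S_tPA < 0) || any(S_PLG < 0))
    stop("bound concentrations must be >= 0", call. = FALSE)
  p$k2 * S_tPA * S_PLG / (p$K_M + S_PLG)
}

#' Free-phase plasmin inhibition rate
#'
#' Second-order inhibition by antiplasmin: rate = k_AP * C_AP * C_PLS,
#' consuming free plasmin and AP 1:1 and producing the inert AP-PLS complex.
#'
#' @param C_PLS free plasmin (uM)
#' @param C_AP free antiplasmin (uM)
#' @param p [kineticParams()]
#' @return inhibition rate (uM/s)
#' @export
plasminInhibitionRate <- function(C_PLS, C_AP, p) {
  if (any(C_PLS < 0) || any(C_AP < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  p$k_AP * C_AP * C_PLS
}

#' Fibrin lysis rate
#'
#' dL/dt = (k_cat / gamma) * S_PLS, forced to zero once the clot is fully
#' lysed (L = n0).
#'
#' @param S_PLS bound plasmin (uM)
#' @param L lysed fibrin (uM)
#' @param n0 initial fibrin (uM)
#' @param p [kineticParams()]
#' @return lysis rate (uM/s)
#' @export
lysisRate <- function(S_PLS, L, n0, p) {
  ifelse(L >= n0, 0, (p$k_cat / p$gamma) * pmax(S_PLS, 0))
}

#' Solubilization fluxes of bound species
#'
#' As fibrin is cut, bound proteins are released back to the free phase in
#' proportion to the fraction of remaining fibrin being lysed:
#' flux_alpha = kappa * S_alpha * (dL/dt) / (n0 - L). The flux leaves the
#' bound phase and enters the free phase 1:1; with kappa = 1 every bound
#' phase reaches exactly zero at complete lysis. The singularity at L = n0 is
#' regularised by flooring the denominator at 1e-6 * n0.
#'
#' @param S named vector of bound concentrations (uM) for tPA, PLG, PLS
#' @param L lysed fibrin (uM)
#' @param lysis_rate dL/dt (uM/s)
#' @param n0 initial fibrin (uM)
#' @param p [kineticParams()]
#' @return named vector of release fluxes (uM/s)
#' @export
solubilizationRates <- function(S, L, lysis_rate, n0, p) {
  if (L < 0 || L > n0 * (1 + 1e-9))
    stop("L must lie in [0, n0]", call. = FALSE)
  denom <- max(n0 - L, 1e-6 * n0)
  p$kappa * pmax(S, 0) * lysis_rate / denom
}

#' Time derivative of the well-mixed state
#'
#' Assembles the full right-hand side over the state vector
#' (F_tPA, F_PLG, F_PLS, F_AP, F_APPLS, S_tPA, S_PLG, S_PLS, L) where
#' F = (V_r + eps) * C is the pooled free amount per clot volume. Clot
#' microstructure (eps, theta) is re-evaluated from L at every call.
#' deSolve-compatible signature.
#'
#' @param t time (s), unused (autonomous system)
#' @param y named state vector
#' @param parms list with elements `kp` ([kineticParams()]) and `mp`
#'   ([microParams()])
#' @return list(dy) as deSolve expects
#' @export
rhsWellMixed <- function(t, y, parms) {
  kp <- parms$kp; mp <- parms$mp
  n0 <- mp$n0_uM
  L <- min(max(y[["L"]], 0), n0)
  rem <- 1 - L / n0                       # (R_f/R_f0)^2
  eps <- 1 - (1 - mp$eps0) * rem
  pool <- kp$plasma_volume_ratio + eps
  rq <- rem^(mp$theta_exponent / 2)
  th_tPA <- mp$theta0_uM[["tPA"]] * rq
  th_P <- mp$theta0_uM[["PLG"]] * rq

  S <- pmax(c(tPA = y[["S_tPA"]], PLG = y[["S_PLG"]], PLS = y[["S_PLS"]]), 0)
  C <- pmax(c(tPA = y[["F_tPA"]], PLG = y[["F_PLG"]], PLS = y[["F_PLS"]],
              AP = y[["F_AP"]], APPLS = y[["F_APPLS"]]), 0) / pool
  if (any(S[c("PLG", "PLS")] > th_P + 1e-3 * mp$theta0_uM[["PLG"]]) ||
      S[["tPA"]] > th_tPA + 1e-3 * mp$theta0_uM[["tPA"]])
    stop("inconsistent state: bound phase exceeds binding-site density",
         call. = FALSE)

  free_tPA <- max(th_tPA - S[["tPA"]], 0)
  free_P <- max(th_P - S[["PLG"]] - S[["PLS"]], 0)
  A <- c(tPA = kp$k_ads[["tPA"]] * C[["tPA"]] * free_tPA -
           kp$k_rev[["tPA"]] * S[["tPA"]],
         PLG = kp$k_ads[["PLG"]] * C[["PLG"]] * free_P -
           kp$k_rev[["PLG"]] * S[["PLG"]],
         PLS = kp$k_ads[["PLS"]] * C[["PLS"]] * free_P -
           kp$k_rev[["PLS"]] * S[["PLS"]])

  G <- plasminGenerationRate(S[["tPA"]], S[["PLG"]], kp)
  dL <- lysisRate(S[["PLS"]], L, n0, kp)
  rel <- solubilizationRates(S, L, dL, n0, kp)
  inh <- plasminInhibitionRate(C[["PLS"]], C[["AP"]], kp)

  dy <- c(
    F_tPA = -A[["tPA"]] + rel[["tPA"]],
    F_PLG = -A[["PLG"]] + rel[["PLG"]],
    F_PLS = -A[["PLS"]] + rel[["PLS"]] - pool * inh - kp$k_loss * y[["F_PLS"]],
    F_AP = -pool * inh,
    F_APPLS = pool * inh,
    S_tPA = A[["tPA"]] - rel[["tPA"]],
    S_PLG = A[["PLG"]] - G - rel[["PLG"]],
    S_PLS = A[["PLS"]] + G - rel[["PLS"]] - kp$k_loss * S[["PLS"]],
    L = dL
  )
  list(dy)
}

#' Simulate the well-mixed fibrinolysis system
#'
#' Integrates the full reaction system with an adaptive stiff-capable solver
#' (deSolve's lsoda; solubilization near complete lysis is stiff). The
#' returned history carries all concentrations plus the derived clot
#' trajectory: fraction lysed, normalised fibre radius, voidage and
#' permeability.
#'
#' @param kp [kineticParams()]
#' @param mp [microParams()]
#' @param C0 named free concentrations (uM): tPA, PLG, PLS, AP
#' @param S0 named bound concentrations (uM): tPA, PLG, PLS
#' @param t_end end time (s)
#' @param rtol,atol solver tolerances
#' @param n_out number of output times
#' @return object of class `wellmixed_history`: data.frame with one row per
#'   output time plus attributes `kp`, `mp`
#' @export
simulateWellMixed <- function(kp, mp,
                              C0 = c(tPA = 0.05, PLG = 1.65, PLS = 0, AP = 1),
                              S0 = c(tPA = 0, PLG = 34.9, PLS = 0),
                              t_end = 150, rtol = 1e-8, atol = 1e-10,
                              n_out = 500) {
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  eps0 <- mp$eps0
  pool0 <- kp$plasma_volume_ratio + eps0
  y0 <- c(F_tPA = unname(C0[["tPA"]]) * pool0,
          F_PLG = unname(C0[["PLG"]]) * pool0,
          F_PLS = unname(C0[["PLS"]]) * pool0,
          F_AP = unname(if ("AP" %in% names(C0)) C0[["AP"]] else 0) * pool0,
          F_APPLS = 0,
          S_tPA = unname(S0[["tPA"]]),
          S_PLG = unname(S0[["PLG"]]),
          S_PLS = unname(S0[["PLS"]]),
          L = 0)
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times, func = rhsWellMixed,
                      parms = list(kp = kp, mp = mp),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integration failed; last valid time ", max(sol[, "time"]),
         " s", call. = FALSE)
  sol <- as.data.frame(sol)
  L <- pmin(pmax(sol$L, 0), mp$n0_uM)
  rem <- 1 - L / mp$n0_uM
  eps <- 1 - (1 - eps0) * rem
  pool <- kp$plasma_volume_ratio + eps
  done <- rem < 1e-6   # complete lysis: bound phases are exactly empty
  h <- data.frame(
    time = sol$time,
    C_tPA = sol$F_tPA / pool, C_PLG = sol$F_PLG / pool,
    C_PLS = sol$F_PLS / pool, C_AP = sol$F_AP / pool,
    C_APPLS = sol$F_APPLS / pool,
    S_tPA = ifelse(done, 0, pmax(sol$S_tPA, 0)),
    S_PLG = ifelse(done, 0, pmax(sol$S_PLG, 0)),
    S_PLS = ifelse(done, 0, pmax(sol$S_PLS, 0)),
    L = L,
    frac_lysed = L / mp$n0_uM,
    Rf_ratio = sqrt(rem),
    voidage = eps,
    permeability = clotPermeability(eps, mp$fibre_radius_nm * sqrt(rem), mp)
  )
  structure(h, class = c("wellmixed_history", "data.frame"), kp = kp, mp = mp)
}

#' Equilibrium plasminogen partition
#'
#' Steady state of the adsorption dynamics with no tPA present: a plasma pool
#' holding `C_PLG_total` uM of plasminogen is contacted with the intact clot
#' and allowed to partition between free and bound phases. Solved from the
#' Langmuir isotherm S = theta0 * C / (K_d + C) under pool mass conservation
#' (V_r + eps0) * C + S = (V_r + eps0) * C_PLG_total.
#'
#' @param kp [kineticParams()]
#' @param mp [microParams()]
#' @param C_PLG_total total plasminogen referred to the pool volume (uM)
#' @return list with `free` (uM) and `bound` (uM per clot volume)
#' @export
equilibratePlg <- function(kp, mp, C_PLG_total = 2) {
  if (C_PLG_total <= 0) stop("C_PLG_total must be > 0", call. = FALSE)
  if (kp$k_ads[["PLG"]] == 0)
    return(list(free = C_PLG_total, bound = 0))
  Kd <- kp$k_rev[["PLG"]] / kp$k_ads[["PLG"]]
  th0 <- mp$theta0_uM[["PLG"]]
  pool <- kp$plasma_volume_ratio + mp$eps0
  f <- function(C) pool * C + th0 * C / (Kd + C) - pool * C_PLG_total
  r <- stats::uniroot(f, c(0, C_PLG_total), tol = 1e-12)
  C <- r$root
  list(free = C, bound = th0 * C / (Kd + C))
}

#' Reference well-mixed initial condition
#'
#' The study protocol: pre-equilibrate the clot with plasminogen, then add
#' tPA (and antiplasmin) to the free pool.
#'
#' @param kp,mp parameter sets
#' @param tPA_uM tPA dose added to the pool (uM); 0.05 = 50 nM
#' @param PLG_total_uM total plasminogen (uM)
#' @param AP_uM antiplasmin (uM)
#' @return list with `C0` and `S0` ready for [simulateWellMixed()]
#' @export
referenceWellMixedInit <- function(kp, mp, tPA_uM = 0.05, PLG_total_uM = 2,
                                   AP_uM = 1) {
  eq <- equilibratePlg(kp, mp, PLG_total_uM)
  list(C0 = c(tPA = tPA_uM, PLG = eq$free, PLS = 0, AP = AP_uM),
       S0 = c(tPA = 0, PLG = eq$bound, PLS = 0))
}

#' Time to reach a lysis fraction
#'
#' First time at which L/n0 >= `fraction`, linearly interpolated between
#' stored snapshots; `NA_real_` if never attained.
#'
#' @param history a `wellmixed_history` (or any data.frame with columns
#'   `time` and `frac_lysed`)
#' @param fraction target lysed fraction in (0, 1]
#' @return time (s), or NA if not reached
#' @export
timeToLysis <- function(history, fraction = 0.95) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (nrow(history) == 0) stop("history is empty", call. = FALSE)
  f <- history$frac_lysed
  i <- which(f >= fraction)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(history$time[1])
  t0 <- history$time[i - 1]; t1 <- history$time[i]
  f0 <- f[i - 1]; f1 <- f[i]
  if (f1 == f0) return(t1)
  t0 + (fraction - f0) / (f1 - f0) * (t1 - t0)
}

#' Well-mixed lysis-time dose response
#'
#' Runs [simulateWellMixed()] across a set of tPA doses and reports the time
#' to a given lysis fraction for each.
#'
#' @param doses_uM tPA doses (uM)
#' @param kp,mp parameter sets
#' @param fraction lysis fraction defining completion
#' @param t_end end time per run (s)
#' @param ... passed to [simulateWellMixed()]
#' @return data.frame(dose_uM, t_lysis_s)
#' @export
doseResponseWellMixed <- function(doses_uM, kp, mp, fraction = 0.95,
                                  t_end = 3600, ...) {
  res <- vapply(doses_uM, function(d) {
    init <- referenceWellMixedInit(kp, mp, tPA_uM = d)
    h <- simulateWellMixed(kp, mp, C0 = init$C0, S0 = init$S0,
                           t_end = t_end, ...)
    timeToLysis(h, fraction)
  }, numeric(1))
  data.frame(dose_uM = doses_uM, t_lysis_s = res)
}
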