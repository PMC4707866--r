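# 1D diffusion-limited transport tier: explicit finite differences (central
# in space, forward in time) for the free species through an occlusive clot,
# local kinetics per cell, and lysis-front metrics.

# pack kinetic + microstructure constants into the flat vector the C++
# kernels expect
packKinPars <- function(kp, mp) {
  c(kp$k_ads[SPECIES], kp$k_rev[SPECIES], kp$k2, kp$K_M, kp$k_cat, kp$gamma,
    kp$kappa, kp$k_loss, mp$eps0, mp$n0_uM,
    mp$theta0_uM[["tPA"]], mp$theta0_uM[["PLG"]], mp$theta_exponent)
}

#' Build a 1D cell-centred grid with an embedded clot
#'
#' @param length_m domain length (m)
#' @param n_cells number of cells
#' @param clot_start_m,clot_end_m clot extent (m); fluid on both sides
#' @return object of class `grid1d`: `x` (cell centres), `dx`, `clot_mask`
#' @export
grid1D <- function(length_m = 3.6e-3, n_cells = 180,
                   clot_start_m = 1e-4, clot_end_m = 3.1e-3) {
  if (length_m <= 0 || n_cells < 2) stop("invalid grid", call. = FALSE)
  if (clot_start_m < 0 || clot_end_m > length_m || clot_start_m >= clot_end_m)
    stop("clot interval must lie inside the domain", call. = FALSE)
  dx <- length_m / n_cells
  x <- (seq_len(n_cells) - 0.5) * dx
  g <- list(length = length_m, n_cells = n_cells, dx = dx, x = x,
            clot_mask = x >= clot_start_m & x < clot_end_m)
  class(g) <- "grid1d"
  g
}

#' Initialise the 1D field
#'
#' Clot cells start plasminogen-equilibrated (bound PLG at its equilibrium
#' value, free PLG at the equilibrium free concentration); fluid cells carry
#' free PLG at the inlet concentration. tPA and plasmin start at zero and
#' enter through the inlet boundary.
#'
#' @param grid [grid1D()]
#' @param kp,mp parameter sets
#' @param inlet named inlet concentrations (uM) for tPA, PLG, PLS
#' @param D named diffusivities (m2/s)
#' @return object of class `field1d`
#' @export
initField1D <- function(grid, kp, mp,
                        inlet = c(tPA = 0.05, PLG = 2, PLS = 0),
                        D = c(tPA = 5e-11, PLG = 5e-11, PLS = 5e-11)) {
  n <- grid$n_cells
  eq <- if (inlet[["PLG"]] > 0) equilibratePlg(kp, mp, inlet[["PLG"]])
        else list(free = 0, bound = 0)
  G <- matrix(0, 3, n, dimnames = list(SPECIES, NULL))
  S <- matrix(0, 3, n, dimnames = list(SPECIES, NULL))
  cm <- grid$clot_mask
  G["PLG", ] <- ifelse(cm, mp$eps0 * eq$free, inlet[["PLG"]])
  S["PLG", cm] <- eq$bound
  f <- list(grid = grid, G = G, S = S, L = numeric(n),
            kp = kp, mp = mp, D = D[SPECIES], inlet = inlet[SPECIES])
  class(f) <- "field1d"
  f
}

# voidage per cell from L (1 outside the clot)
fieldVoidage <- function(f) {
  eps <- rep(1, f$grid$n_cells)
  cm <- f$grid$clot_mask
  eps[cm] <- 1 - (1 - f$mp$eps0) * (1 - f$L[cm] / f$mp$n0_uM)
  eps
}

#' Advance the 1D field by one explicit step
#'
#' One forward-Euler transport step (central-difference diffusion of the free
#' species, Dirichlet inlet, zero-gradient outlet) followed by the local
#' kinetics update with explicit substeps. Errors if `dt` violates the
#' diffusive stability bound dt <= safety * dx^2 / (2 max D).
#'
#' @param f [initField1D()] field
#' @param dt time step (s)
#' @param safety stability safety factor
#' @param kin_dt kinetics substep target (s)
#' @param inlet_dirichlet fix the inlet concentration (default); `FALSE`
#'   makes both ends zero-flux (closed domain)
#' @return updated `field1d`
#' @export
stepDiffusionReaction <- function(f, dt, safety = 1, kin_dt = 0.02,
                                  inlet_dirichlet = TRUE) {
  bound <- safety * f$grid$dx^2 / (2 * max(f$D))
  if (dt > bound)
    stop(sprintf("dt = %g s violates the diffusive stability bound %g s",
                 dt, bound), call. = FALSE)
  nsub <- max(1L, ceiling(dt / kin_dt))
  out <- cpp_advance_1d(f$G, f$S, f$L, f$grid$clot_mask, numeric(0),
                        unname(f$D), f$grid$dx, dt, 1L, nsub,
                        unname(f$inlet), inlet_dirichlet,
                        packKinPars(f$kp, f$mp))
  f$G <- out$G; f$S <- out$S; f$L <- out$L
  dimnames(f$G) <- dimnames(f$S) <- list(SPECIES, NULL)
  f
}

#' Position of the lysis front
#'
#' Coordinate of the farthest clot cell whose lysed fraction has reached
#' `threshold`; `-Inf` when no cell qualifies yet.
#'
#' @param L per-cell lysed fibrin (uM)
#' @param grid [grid1D()]
#' @param n0 initial fibrin (uM)
#' @param threshold lysed-fraction threshold
#' @return front coordinate (m) or -Inf
#' @export
lysisFrontPosition <- function(L, grid, n0, threshold = 0.95) {
  idx <- which(grid$clot_mask & L / n0 >= threshold)
  if (length(idx) == 0) return(-Inf)
  grid$x[max(idx)]
}

#' Simulate 1D diffusion-limited clot lysis
#'
#' Explicit finite-difference integration of the reaction-diffusion system
#' with profile snapshots and a lysis-front timeline.
#'
#' @param grid [grid1D()]
#' @param kp,mp parameter sets
#' @param inlet,D as in [initField1D()]
#' @param t_end end time (s); default 90 min
#' @param snapshot_times times (s) at which to store full profiles
#' @param metric_dt cadence (s) of the front-position timeline
#' @param dt_safety diffusive stability safety factor
#' @param kin_dt kinetics substep (s)
#' @return object of class `sim1d_history`: list with `front` timeline
#'   data.frame (time, position), `snapshots` (named list of profile
#'   data.frames), `final` field, `grid`, parameter sets
#' @export
simulate1D <- function(grid = grid1D(), kp = kineticParams(),
                       mp = microParams(),
                       inlet = c(tPA = 0.05, PLG = 2, PLS = 0),
                       D = c(tPA = 5e-11, PLG = 5e-11, PLS = 5e-11),
                       t_end = 5400,
                       snapshot_times = c(10, 30, 50, 70, 90) * 60,
                       metric_dt = 30, dt_safety = 0.4, kin_dt = 0.02) {
  f <- initField1D(grid, kp, mp, inlet, D)
  dt <- dt_safety * grid$dx^2 / (2 * max(f$D))
  nsub <- max(1L, ceiling(dt / kin_dt))
  pars <- packKinPars(kp, mp)
  snapshot_times <- sort(snapshot_times[snapshot_times <= t_end])
  marks <- sort(unique(c(seq(metric_dt, t_end, by = metric_dt),
                         snapshot_times, t_end)))
  t_now <- 0
  front <- data.frame(time = 0, position = -Inf)
  snaps <- list()
  for (tm in marks) {
    n_steps <- max(0L, round((tm - t_now) / dt))
    if (n_steps > 0) {
      out <- cpp_advance_1d(f$G, f$S, f$L, grid$clot_mask, numeric(0),
                            unname(f$D), grid$dx, dt, n_steps, nsub,
                            unname(f$inlet), TRUE, pars)
      f$G <- out$G; f$S <- out$S; f$L <- out$L
      t_now <- t_now + n_steps * dt
    }
    front <- rbind(front, data.frame(
      time = t_now,
      position = lysisFrontPosition(f$L, grid, mp$n0_uM)))
    if (any(abs(snapshot_times - tm) < metric_dt / 2)) {
      eps <- fieldVoidage(f)
      snaps[[sprintf("t%ds", round(t_now))]] <- data.frame(
        x = grid$x,
        C_tPA = f$G["tPA", ] / eps, C_PLG = f$G["PLG", ] / eps,
        C_PLS = f$G["PLS", ] / eps,
        S_tPA = f$S["tPA", ], S_PLG = f$S["PLG", ], S_PLS = f$S["PLS", ],
        L = f$L, frac_lysed = ifelse(grid$clot_mask, f$L / mp$n0_uM, NA))
    }
  }
  dimnames(f$G) <- dimnames(f$S) <- list(SPECIES, NULL)
  structure(list(front = front, snapshots = snaps, final = f, grid = grid,
                 kp = kp, mp = mp, t_end = t_end),
            class = "sim1d_history")
}

#' @export
print.sim1d_history <- function(x, ...) {
  cat("<sim1d_history>\n")
  cat(sprintf("  t_end = %g s, %d snapshots, final front at %s m\n",
              x$t_end, length(x$snapshots),
              format(utils::tail(x$front$position, 1))))
  invisible(x)
}

#' Average lysis-front velocity
#'
#' Front displacement between `t_start` and `t_end` (defaults 10 and 80 min)
#' divided by the elapsed time, in um/min. The front position at each end is
#' interpolated from the stored timeline.
#'
#' @param history [simulate1D()] result
#' @param t_start,t_end window (s)
#' @return velocity (um/min)
#' @export
frontVelocity <- function(history, t_start = 600, t_end = 4800) {
  fr <- history$front
  if (max(fr$time) < t_end)
    stop("history does not cover the requested window", call. = FALSE)
  posAt <- function(tt) {
    ok <- is.finite(fr$position)
    if (!any(ok & fr$time <= tt))
      stop("front not yet formed at t = ", tt,
           " s; allow a longer spin-up", call. = FALSE)
    stats::approx(fr$time[ok], fr$position[ok], xout = tt, rule = 2)$y
  }
  (posAt(t_end) - posAt(t_start)) / (t_end - t_start) * 6e7
}

#' Peak height and width of a concentration profile
#'
#' Height of the profile maximum and its full width at half maximum, with the
#' half-maximum crossings located by linear interpolation between cell
#' centres (sub-cell resolution, so width trends are not quantised by the
#' grid). Used to track how the bound-protein front becomes shorter and wider
#' as lysis proceeds.
#'
#' @param y profile values (one per cell)
#' @param x cell-centre coordinates (m)
#' @return list with `peak` and `fwhm` (m)
#' @export
peakMetrics <- function(y, x) {
  stopifnot(length(y) == length(x))
  i <- which.max(y)
  half <- y[i] / 2
  left <- x[1]
  if (any(y[seq_len(i)] < half)) {
    j <- max(which(y[seq_len(i)] < half))
    left <- x[j] + (half - y[j]) / (y[j + 1] - y[j]) * (x[j + 1] - x[j])
  }
  right <- x[length(x)]
  if (any(y[i:length(y)] < half)) {
    j <- i - 1 + min(which(y[i:length(y)] < half))
    right <- x[j - 1] + (half - y[j - 1]) / (y[j] - y[j - 1]) * (x[j] - x[j - 1])
  }
  list(peak = y[i], fwhm = right - left)
}

#' Lysis-front velocity across tPA doses
#'
#' Runs [simulate1D()] once per inlet tPA dose and reports the average front
#' velocity for each.
#'
#' @param doses_uM inlet tPA doses (uM)
#' @param ... passed to [simulate1D()]
#' @return data.frame(dose_uM, velocity_um_min)
#' @export
doseSweep1D <- function(doses_uM, ...) {
  if (any(doses_uM <= 0)) stop("doses must be > 0", call. = FALSE)
  v <- vapply(doses_uM, function(d) {
    h <- simulate1D(inlet = c(tPA = d, PLG = 2, PLS = 0), ...)
    frontVelocity(h)
  }, numeric(1))
  data.frame(dose_uM = doses_uM, velocity_um_min = v)
}
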