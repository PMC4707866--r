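# Coupled 2D tier: species advection-diffusion-reaction over the evolving
# clot with quasi-steady flow updates. Free species are advanced with an
# implicit (backward-Euler) first-order-upwind advection + central-diffusion
# operator, factorised once per flow update and reused; kinetics are advanced
# by the explicit substepped kernel shared with the 1D tier. Flow is re-solved
# whenever the voidage field has drifted by more than a set tolerance, with
# the lysis-driven voidage change entering continuity as a mass source.

# cell index helper: column-major over nx * ny, id = (j-1)*nx + i

# Build the implicit transport operator M = I - dt*Lop (Lop = -div flux) for
# one diffusivity, plus the inlet-boundary rhs coefficient vector (to be
# multiplied by the inlet concentration each step).
buildTransportOp <- function(grid, flow, eps, D, dt) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx; dy <- grid$dy
  N <- nx * ny
  id <- function(i, j) (j - 1) * nx + i
  ti <- list(); tj <- list(); tx <- list(); nb <- 0
  add <- function(r, c, x) {
    nb <<- nb + 1; ti[[nb]] <<- r; tj[[nb]] <<- c; tx[[nb]] <<- x
  }
  epsm <- eps

  ## interior x-faces between (i-1,j) and (i,j), i = 2..nx
  gi <- rep(2:nx, times = ny); gj <- rep(seq_len(ny), each = nx - 1)
  cL <- id(gi - 1, gj); cR <- id(gi, gj)
  uf <- flow$u[cbind(gi, gj)]
  aL <- pmax(uf, 0) / epsm[cL] + D / (dx * epsm[cL])
  aR <- pmin(uf, 0) / epsm[cR] - D / (dx * epsm[cR])
  add(cL, cL, dt * aL / dx); add(cL, cR, dt * aR / dx)
  add(cR, cL, -dt * aL / dx); add(cR, cR, -dt * aR / dx)

  ## interior y-faces between (i,j-1) and (i,j), j = 2..ny
  gi <- rep(seq_len(nx), times = ny - 1); gj <- rep(2:ny, each = nx)
  cS <- id(gi, gj - 1); cN <- id(gi, gj)
  vf <- flow$v[cbind(gi, gj)]
  aS <- pmax(vf, 0) / epsm[cS] + D / (dy * epsm[cS])
  aN <- pmin(vf, 0) / epsm[cN] - D / (dy * epsm[cN])
  add(cS, cS, dt * aS / dy); add(cS, cN, dt * aN / dy)
  add(cN, cS, -dt * aS / dy); add(cN, cN, -dt * aN / dy)

  ## inlet faces (i = 1): Dirichlet concentration via mirror ghost
  gj <- seq_len(ny); c1 <- id(1, gj)
  uf <- flow$u[cbind(rep(1, ny), gj)]
  # influx uf*C_in (when uf>0) and diffusive 2D/dx*(C_in - C_1)
  add(c1, c1, dt * (2 * D / (dx^2 * epsm[c1]) - pmin(uf, 0) / (dx * epsm[c1])))
  rhs_coef <- numeric(N)
  rhs_coef[c1] <- dt * (pmax(uf, 0) / dx + 2 * D / dx^2)

  ## outlet faces (i = nx+1): zero-gradient; advective outflow upwind
  cN <- id(nx, gj)
  uf <- flow$u[cbind(rep(nx + 1, ny), gj)]
  add(cN, cN, dt * uf / (dx * epsm[cN]))

  M <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(N, N)) + Matrix::Diagonal(N)
  list(fac = Matrix::lu(M), rhs_coef = rhs_coef)
}

#' Advance the 2D free-species fields by one implicit transport step
#'
#' Backward-Euler upwind advection + central diffusion of the superficial
#' concentrations, followed by the local kinetics update. Intended for tests
#' and custom drivers; [simulateOcclusionLysis()] amortises the operator
#' factorisation, which this convenience wrapper rebuilds per call.
#'
#' @param fields list with `G` (3 x N superficial concentrations, rows tPA,
#'   PLG, PLS), `S` (3 x N bound), `L` (length-N lysed fibrin); cells indexed
#'   column-major over the grid
#' @param flow [solveFlow()] field
#' @param grid [buildChannel()] grid
#' @param dt time step (s)
#' @param kp,mp parameter sets
#' @param inlet named inlet concentrations (uM)
#' @param D diffusivity (m2/s), common to the three species
#' @param kin_dt kinetics substep (s); set `Inf` to skip kinetics
#' @return updated `fields`
#' @export
transportStep2D <- function(fields, flow, grid, dt, kp, mp,
                            inlet = c(tPA = 0.05, PLG = 2, PLS = 0),
                            D = 5e-11, kin_dt = 0.02) {
  eps <- cellVoidage2D(fields$L, grid, mp)
  op <- buildTransportOp(grid, flow, eps, D, dt)
  for (s in seq_len(3))
    fields$G[s, ] <- as.numeric(Matrix::solve(
      op$fac, fields$G[s, ] + op$rhs_coef * inlet[[SPECIES[s]]]))
  if (is.finite(kin_dt)) {
    nsub <- max(1L, ceiling(dt / kin_dt))
    out <- cpp_kinetics_advance(fields$G, fields$S, fields$L,
                                as.vector(grid$clot_mask), dt, nsub,
                                packKinPars(kp, mp))
    fields$G <- out$G; fields$S <- out$S; fields$L <- out$L
  }
  fields
}

# per-cell voidage from lysed fibrin (1 outside the clot)
cellVoidage2D <- function(L, grid, mp) {
  eps <- rep(1, grid$nx * grid$ny)
  cm <- as.vector(grid$clot_mask)
  eps[cm] <- 1 - (1 - mp$eps0) * (1 - L[cm] / mp$n0_uM)
  eps
}

# initial coupled fields: clot plasminogen-equilibrated, fluid at inlet PLG
initFields2D <- function(grid, kp, mp, inlet) {
  N <- grid$nx * grid$ny
  eq <- equilibratePlg(kp, mp, inlet[["PLG"]])
  G <- matrix(0, 3, N, dimnames = list(SPECIES, NULL))
  S <- matrix(0, 3, N, dimnames = list(SPECIES, NULL))
  cm <- as.vector(grid$clot_mask)
  G["PLG", ] <- ifelse(cm, mp$eps0 * eq$free, inlet[["PLG"]])
  S["PLG", cm] <- eq$bound
  list(G = G, S = S, L = numeric(N))
}

#' Simulate lysis of a fully occluding clot under a pressure drop
#'
#' The full coupled model: steady flow is first established across the intact
#' occlusion, then tPA (and plasminogen) enter at the inlet and the loop
#' alternates implicit species transport, local fibrinolysis kinetics, and
#' quasi-steady flow re-solves whenever the voidage field has changed by more
#' than `flow_eps_tol` anywhere (the accumulated voidage change supplies the
#' continuity mass source). The run records a lysed-fraction and free-tPA
#' history and the breakthrough-ratio (BTR) bookkeeping: BTR time zero is the
#' first cell reaching 1% lysis and breakthrough is the first cell of the
#' clot-exit column reaching 95%.
#'
#' @param grid [buildChannel()] grid
#' @param kp,mp,fluid parameter sets
#' @param dp pressure drop (Pa)
#' @param inlet named inlet concentrations (uM)
#' @param D free-species diffusivity (m2/s)
#' @param t_end wall-clock end of simulated time (s)
#' @param stop_btr stop once the BTR reaches this value (Inf = run to t_end)
#' @param dt_max largest transport step (s)
#' @param cfl advective step bound as a multiple of dx/max|u| (implicit
#'   scheme: values above 1 trade front sharpness for speed)
#' @param kin_dt kinetics substep (s)
#' @param flow_eps_tol voidage drift that triggers a flow re-solve
#' @param metric_dt cadence (s) of history recording and event detection
#' @param snapshot_btr BTR values at which to keep labelled field snapshots
#' @param verbose print per-interval progress
#' @return list with `history` (class `lysis_history`: times, lysed-fraction
#'   and free-tPA fields, flow-update log) and `metrics` (class
#'   `lysis_metrics`: t_start, t_breakthrough, breakthrough cell, funnel
#'   widths, asymmetry/recirculation at BTR marks)
#' @export
simulateOcclusionLysis <- function(grid, kp = kineticParams(),
                                   mp = microParams(), fluid = fluidProps(),
                                   dp = 1,
                                   inlet = c(tPA = 0.05, PLG = 2, PLS = 0),
                                   D = 5e-11, t_end = 20000, stop_btr = Inf,
                                   dt_max = 0.25, cfl = 2, kin_dt = 0.02,
                                   flow_eps_tol = 0.01, metric_dt = 10,
                                   snapshot_btr = seq(0.5, 2.5, by = 0.25),
                                   verbose = FALSE) {
  nx <- grid$nx; ny <- grid$ny; N <- nx * ny
  cm <- as.vector(grid$clot_mask)
  exit_col <- max(which(rowSums(grid$clot_mask) > 0))
  n0 <- mp$n0_uM
  f <- initFields2D(grid, kp, mp, inlet)
  pars <- packKinPars(kp, mp)
  clot_cells_per_col <- function(i) which(cm & rep(seq_len(nx), ny) == i)

  solveCurrentFlow <- function(L, eps_prev, dt_elapsed, warm) {
    eps <- cellVoidage2D(L, grid, mp)
    rem <- ifelse(cm, 1 - L / n0, 1)
    kperm <- matrix(mp$k_max_m2, nx, ny)
    kperm[cm] <- clotPermeability(pmin(eps[cm], 1),
                                  mp$fibre_radius_nm * sqrt(rem[cm]), mp)
    src <- if (is.null(eps_prev) || dt_elapsed <= 0) NULL
           else matrix(-(eps - eps_prev) / dt_elapsed, nx, ny)
    solveFlow(grid, kperm, matrix(eps, nx, ny), dp, fluid, mp,
              mass_source = src, warm_start = warm)
  }

  flow <- solveCurrentFlow(f$L, NULL, 0, NULL)
  eps_ref <- cellVoidage2D(f$L, grid, mp)
  t_ref <- 0
  ops <- NULL
  dtCurrent <- function(flow) {
    umax <- max(abs(flow$u) / grid$dx, abs(flow$v) / grid$dy, 1e-12)
    min(dt_max, cfl / umax)
  }
  dt <- dtCurrent(flow)
  ops <- buildTransportOp(grid, flow, eps_ref, D, dt)
  nsub <- max(1L, ceiling(dt / kin_dt))

  times <- 0; fracs <- list(matrix(0, nx, ny)); ctpa <- list(matrix(0, nx, ny))
  flow_log <- data.frame(time = 0, dt = dt, umax = max(abs(flow$u)))
  t_start <- NA_real_; t_bt <- NA_real_; bt_cell <- c(NA, NA)
  funnel_width <- NULL
  btr_marks <- list()
  snaps <- list()

  t <- 0
  while (t < t_end) {
    t_next <- min(t + metric_dt, t_end)
    while (t < t_next - 1e-9) {
      step <- min(dt, t_next - t)
      if (step < dt * 0.999) {   # short closing step: rebuild for this dt
        op_s <- buildTransportOp(grid, flow, eps_ref, D, step)
        for (s in 1:3)
          f$G[s, ] <- as.numeric(Matrix::solve(
            op_s$fac, f$G[s, ] + op_s$rhs_coef * inlet[[SPECIES[s]]]))
      } else {
        for (s in 1:3)
          f$G[s, ] <- as.numeric(Matrix::solve(
            ops$fac, f$G[s, ] + ops$rhs_coef * inlet[[SPECIES[s]]]))
      }
      out <- cpp_kinetics_advance(f$G, f$S, f$L, cm, step,
                                  max(1L, ceiling(step / kin_dt)), pars)
      f$G <- out$G; f$S <- out$S; f$L <- out$L
      t <- t + step
    }

    ## events, metrics, history
    frac <- f$L / n0
    if (is.na(t_start) && any(frac[cm] >= 0.01)) t_start <- t
    if (is.na(t_bt)) {
      ec <- clot_cells_per_col(exit_col)
      hit <- ec[frac[ec] >= 0.95]
      if (length(hit) > 0) {
        t_bt <- t
        jbt <- (hit - 1) %/% nx + 1
        bt_cell <- c(exit_col, jbt[which.min(abs(grid$yc[jbt] - grid$height / 2))])
        cols <- which(rowSums(grid$clot_mask) > 0)
        funnel_width <- vapply(cols, function(i)
          sum(frac[clot_cells_per_col(i)] >= 0.95) * grid$dy, numeric(1))
      }
    }
    btr <- if (!is.na(t_bt)) (t - t_start) / (t_bt - t_start) else NA_real_
    times <- c(times, t)
    fracs[[length(fracs) + 1]] <- matrix(frac, nx, ny)
    eps_now <- cellVoidage2D(f$L, grid, mp)
    ctpa[[length(ctpa) + 1]] <- matrix(f$G["tPA", ] / eps_now, nx, ny)

    if (!is.na(btr)) {
      for (bm in c(1.2, 1.5)) {
        key <- sprintf("btr%.2f", bm)
        if (btr >= bm && is.null(btr_marks[[key]])) {
          rc <- recirculationMetrics(flow, grid, grid$clot_mask)
          Fm <- matrix(frac, nx, ny)
          asym <- sum(abs(Fm - Fm[, ny:1])) / max(2 * sum(Fm), 1e-12)
          btr_marks[[key]] <- list(btr = bm, time = t, recirc = rc,
                                   lysed_asymmetry = asym)
        }
      }
      for (bm in snapshot_btr) {
        key <- sprintf("snap%.2f", bm)
        if (btr >= bm && is.null(snaps[[key]]))
          snaps[[key]] <- list(btr = bm, time = t, frac = matrix(frac, nx, ny))
      }
    }
    if (verbose)
      message(sprintf("t = %.0f s, lysed %.3f, BTR %s, dt %.3g",
                      t, mean(frac[cm]),
                      ifelse(is.na(btr), "-", sprintf("%.2f", btr)), dt))
    if (!is.na(btr) && btr >= stop_btr) break
    if (all(frac[cm] >= 1 - 1e-9)) break

    ## quasi-steady flow update on voidage drift
    if (max(abs(eps_now - eps_ref)) > flow_eps_tol) {
      flow <- solveCurrentFlow(f$L, eps_ref, t - t_ref, flow)
      eps_ref <- eps_now; t_ref <- t
      dt <- dtCurrent(flow)
      ops <- buildTransportOp(grid, flow, eps_ref, D, dt)
      flow_log <- rbind(flow_log,
                        data.frame(time = t, dt = dt, umax = max(abs(flow$u))))
    }
  }

  history <- structure(list(time = times, frac = fracs, C_tPA = ctpa,
                            grid = grid, exit_col = exit_col, mp = mp,
                            flow_log = flow_log, snapshots = snaps),
                       class = "lysis_history")
  metrics <- structure(list(dp = dp, t_start = t_start, t_breakthrough = t_bt,
                            breakthrough_cell = bt_cell,
                            funnel_width = funnel_width,
                            btr_marks = btr_marks,
                            final_flow = flow, final_fields = f),
                       class = "lysis_metrics")
  list(history = history, metrics = metrics)
}

#' @export
print.lysis_metrics <- function(x, ...) {
  cat(sprintf("<lysis_metrics> dp = %g Pa: lysis onset %s s, breakthrough %s s\n",
              x$dp, format(x$t_start), format(x$t_breakthrough)))
  invisible(x)
}

#' Breakthrough-ratio timeline of a lysis history
#'
#' BTR(t) = (t - t_start) / (t_breakthrough - t_start) with t_start the first
#' recorded time at which any clot cell is at least 1% lysed and breakthrough
#' the first time any cell of the clot-exit column is at least 95% lysed.
#' BTR is NA before onset and after the end of data when breakthrough never
#' happened.
#'
#' @param history a `lysis_history` from [simulateOcclusionLysis()], or any
#'   list with `time`, `frac` (list of nx x ny lysed-fraction matrices),
#'   `exit_col` and `grid`
#' @return data.frame(time, btr); attributes `t_start`, `t_breakthrough`
#' @export
breakthroughRatio <- function(history) {
  cm <- history$grid$clot_mask
  exit_cells <- which(cm[history$exit_col, ])
  t_start <- NA_real_; t_bt <- NA_real_
  for (k in seq_along(history$time)) {
    Fm <- history$frac[[k]]
    if (is.na(t_start) && any(Fm[cm] >= 0.01)) t_start <- history$time[k]
    if (is.na(t_bt) && any(Fm[history$exit_col, exit_cells] >= 0.95))
      t_bt <- history$time[k]
    if (!is.na(t_start) && !is.na(t_bt)) break
  }
  btr <- if (is.na(t_start) || is.na(t_bt)) rep(NA_real_, length(history$time))
         else (history$time - t_start) / (t_bt - t_start)
  btr[history$time < t_start] <- NA_real_
  structure(data.frame(time = history$time, btr = btr),
            t_start = t_start, t_breakthrough = t_bt)
}

#' Compare occlusion lysis across pressure drops
#'
#' Runs [simulateOcclusionLysis()] for each pressure drop and tabulates
#' breakthrough times and the recirculation/asymmetry metrics at matched BTR
#' checkpoints (1.2 and 1.5). Per-run failures are reported in the table and
#' do not abort the sweep.
#'
#' @param dp_list pressure drops (Pa)
#' @param ... passed to [simulateOcclusionLysis()] (grid, parameters, ...)
#' @param stop_btr how far past breakthrough to run each case
#' @return data.frame with one row per pressure drop: t_start,
#'   t_breakthrough, recirculation areas and asymmetries at BTR 1.2/1.5
#' @export
comparePressureDrops <- function(dp_list, ..., stop_btr = 1.55) {
  if (length(dp_list) == 0) stop("dp_list is empty", call. = FALSE)
  rows <- lapply(dp_list, function(dp) {
    res <- tryCatch(
      simulateOcclusionLysis(dp = dp, stop_btr = stop_btr, ...),
      error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(dp = dp, t_start = NA, t_breakthrough = NA,
                        recirc_area_12 = NA, recirc_area_15 = NA,
                        asym_12 = NA, asym_15 = NA,
                        error = conditionMessage(res)))
    m <- res$metrics
    g <- function(key, fld)
      if (!is.null(m$btr_marks[[key]])) m$btr_marks[[key]][[fld]] else NA
    data.frame(
      dp = dp, t_start = m$t_start, t_breakthrough = m$t_breakthrough,
      recirc_area_12 = {
        r <- g("btr1.20", "recirc")
        if (is.list(r)) r$area_top + r$area_bottom else NA
      },
      recirc_area_15 = {
        r <- g("btr1.50", "recirc")
        if (is.list(r)) r$area_top + r$area_bottom else NA
      },
      asym_12 = g("btr1.20", "lysed_asymmetry"),
      asym_15 = g("btr1.50", "lysed_asymmetry"),
      error = NA_character_)
  })
  do.call(rbind, rows)
}
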