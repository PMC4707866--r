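# Volume-averaged incompressible flow in a channel with a permeable clot:
# steady momentum with a Darcy resistance -(mu/k) u active in clot cells,
# solved monolithically (velocities + pressure on a staggered MAC grid,
# sparse direct factorisation) with Picard-lagged first-order upwind
# convection. Superficial-velocity formulation: one momentum equation valid
# in both open fluid and clot.

#' Build a 2D channel grid with a fully occluding clot
#'
#' Cell-centred staggered grid of a straight channel with a rectangular clot
#' spanning the full height. Default proportions place the clot 5 clot-widths
#' from the inlet with 10 clot-widths of downstream run-out, so inlet/outlet
#' boundaries do not influence the flow near the clot.
#'
#' @param height_m channel height (m); default 5 mm, an average cerebral
#'   artery diameter
#' @param clot_width_m clot streamwise width (m); default 2.5 mm
#' @param upstream_m,downstream_m fluid run lengths before/after the clot (m);
#'   defaults 5 and 10 clot widths
#' @param nx,ny grid resolution
#' @return object of class `grid2d`: dims, spacings, cell centres `xc`, `yc`,
#'   clot mask (nx x ny), clot interval
#' @export
buildChannel <- function(height_m = 5e-3, clot_width_m = 2.5e-3,
                         upstream_m = 5 * clot_width_m,
                         downstream_m = 10 * clot_width_m,
                         nx = 160, ny = 40) {
  length_m <- upstream_m + clot_width_m + downstream_m
  if (clot_width_m <= 0 || upstream_m < 0 || downstream_m < 0)
    stop("clot must lie inside the channel", call. = FALSE)
  dx <- length_m / nx; dy <- height_m / ny
  if (clot_width_m / dx < 8)
    stop("need at least 8 cells across the clot", call. = FALSE)
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  clot_x0 <- upstream_m; clot_x1 <- upstream_m + clot_width_m
  mask <- matrix(xc >= clot_x0 & xc < clot_x1, nx, ny)
  g <- list(nx = nx, ny = ny, dx = dx, dy = dy,
            length = length_m, height = height_m,
            xc = xc, yc = yc, clot_mask = mask,
            clot_x0 = clot_x0, clot_x1 = clot_x1)
  class(g) <- "grid2d"
  g
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %g x %g mm, %d x %d cells, clot [%g, %g] mm\n",
              x$length * 1e3, x$height * 1e3, x$nx, x$ny,
              x$clot_x0 * 1e3, x$clot_x1 * 1e3))
  invisible(x)
}

# shift a matrix, replicating the edge (used for clamped neighbour lookups)
shiftEdge <- function(M, di, dj) {
  nr <- nrow(M); nc <- ncol(M)
  ri <- pmin(pmax(seq_len(nr) + di, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dj, 1), nc)
  M[ri, ci, drop = FALSE]
}

# lagged upwind convection terms rho*(u.grad)u at u- and v-faces
convectionTerms <- function(u, v, grid, rho) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx; dy <- grid$dy
  # ghosts: zero-gradient at inlet/outlet, no-slip mirror at walls
  uw <- rbind(u[1, ], u)[seq_len(nx + 1), , drop = FALSE]       # u_{i-1}
  ue <- rbind(u[-1, , drop = FALSE], u[nx + 1, ])               # u_{i+1}
  us <- cbind(-u[, 1], u)[, seq_len(ny), drop = FALSE]          # u_{i,j-1}
  un <- cbind(u[, -1, drop = FALSE], -u[, ny])                  # u_{i,j+1}
  # average the 4 v-faces around each u-face (edge columns clamped)
  iW <- pmax(seq_len(nx + 1) - 1, 1); iE <- pmin(seq_len(nx + 1), nx)
  vb <- 0.25 * (v[iW, 1:ny, drop = FALSE] + v[iW, 2:(ny + 1), drop = FALSE] +
                v[iE, 1:ny, drop = FALSE] + v[iE, 2:(ny + 1), drop = FALSE])
  dudx <- ifelse(u > 0, (u - uw) / dx, (ue - u) / dx)
  dudy <- ifelse(vb > 0, (u - us) / dy, (un - u) / dy)
  conv_u <- rho * (u * dudx + vb * dudy)

  vw <- rbind(v[1, ], v)[seq_len(nx), , drop = FALSE]
  ve <- rbind(v[-1, , drop = FALSE], v[nx, ])
  vs <- cbind(v[, 1] * 0, v)[, seq_len(ny + 1), drop = FALSE]   # v=0 below wall
  vn <- cbind(v[, -1, drop = FALSE], v[, ny + 1] * 0)
  jS <- pmax(seq_len(ny + 1) - 1, 1); jN <- pmin(seq_len(ny + 1), ny)
  ub <- 0.25 * (u[1:nx, jS, drop = FALSE] + u[2:(nx + 1), jS, drop = FALSE] +
                u[1:nx, jN, drop = FALSE] + u[2:(nx + 1), jN, drop = FALSE])
  dvdx <- ifelse(ub > 0, (v - vw) / dx, (ve - v) / dx)
  dvdy <- ifelse(v > 0, (v - vs) / dy, (vn - v) / dy)
  conv_v <- rho * (ub * dvdx + v * dvdy)
  list(u = conv_u, v = conv_v)
}

# assemble the steady Stokes-Brinkman saddle-point matrix (convection and
# pressure-BC constants live on the right-hand side)
assembleFlowMatrix <- function(grid, resist, fluid) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx; dy <- grid$dy
  mu <- fluid$viscosity
  Nu <- (nx + 1) * ny; Nv <- nx * (ny + 1)
  iu <- function(i, j) (j - 1) * (nx + 1) + i
  iv <- function(i, j) Nu + (j - 1) * nx + i
  ip <- function(i, j) Nu + Nv + (j - 1) * nx + i
  ti <- vector("list", 24); tj <- vector("list", 24); tx <- vector("list", 24)
  nblk <- 0
  add <- function(r, c, x) {
    nblk <<- nblk + 1
    ti[[nblk]] <<- r; tj[[nblk]] <<- c; tx[[nblk]] <<- x
  }

  ## u-momentum rows, faces i = 1..nx+1, j = 1..ny
  gi <- rep(seq_len(nx + 1), times = ny)
  gj <- rep(seq_len(ny), each = nx + 1)
  rows <- iu(gi, gj)
  # Darcy resistance at the face: mean of adjacent cells (edge: single cell)
  rW <- resist[cbind(pmax(gi - 1, 1), gj)]
  rE <- resist[cbind(pmin(gi, nx), gj)]
  rf <- 0.5 * (rW + rE)
  ax <- mu / dx^2; ay <- mu / dy^2
  ac <- rep(-2 * ax - 2 * ay, length(rows)) - rf
  # wall mirror ghosts: u_ghost = -u -> centre picks up an extra -mu/dy^2
  ac <- ac - ifelse(gj == 1, ay, 0) - ifelse(gj == ny, ay, 0)
  # inlet/outlet zero-gradient ghosts: centre gains +mu/dx^2
  ac <- ac + ifelse(gi == 1 | gi == nx + 1, ax, 0)
  add(rows, rows, ac)
  w <- gi > 1;       add(rows[w], iu(gi[w] - 1, gj[w]), rep(ax, sum(w)))
  w <- gi < nx + 1;  add(rows[w], iu(gi[w] + 1, gj[w]), rep(ax, sum(w)))
  w <- gj > 1;       add(rows[w], iu(gi[w], gj[w] - 1), rep(ay, sum(w)))
  w <- gj < ny;      add(rows[w], iu(gi[w], gj[w] + 1), rep(ay, sum(w)))
  # pressure gradient -(pE - pW)/dx; boundary faces use mirror ghosts around
  # the fixed boundary pressure (handled via doubled coefficient + rhs const)
  w <- gi > 1 & gi < nx + 1
  add(rows[w], ip(gi[w] - 1, gj[w]), rep(1 / dx, sum(w)))
  add(rows[w], ip(gi[w], gj[w]), rep(-1 / dx, sum(w)))
  w <- gi == 1
  add(rows[w], ip(1, gj[w]), rep(-2 / dx, sum(w)))
  w <- gi == nx + 1
  add(rows[w], ip(nx, gj[w]), rep(2 / dx, sum(w)))

  ## v-momentum rows, faces i = 1..nx, j = 2..ny (j = 1, ny+1 are wall rows)
  gi <- rep(seq_len(nx), times = ny - 1)
  gj <- rep(2:ny, each = nx)
  rows <- iv(gi, gj)
  rS <- resist[cbind(gi, gj - 1)]
  rN <- resist[cbind(gi, gj)]
  rf <- 0.5 * (rS + rN)
  ac <- rep(-2 * ax - 2 * ay, length(rows)) - rf
  ac <- ac + ifelse(gi == 1 | gi == nx, ax, 0)   # zero-gradient side ghosts
  add(rows, rows, ac)
  w <- gi > 1;  add(rows[w], iv(gi[w] - 1, gj[w]), rep(ax, sum(w)))
  w <- gi < nx; add(rows[w], iv(gi[w] + 1, gj[w]), rep(ax, sum(w)))
  add(rows, iv(gi, gj - 1), rep(ay, length(rows)))
  add(rows, iv(gi, gj + 1), rep(ay, length(rows)))
  add(rows, ip(gi, gj - 1), rep(1 / dy, length(rows)))
  add(rows, ip(gi, gj), rep(-1 / dy, length(rows)))
  # wall rows: v = 0
  gi <- rep(seq_len(nx), 2); gj <- rep(c(1, ny + 1), each = nx)
  rows <- iv(gi, gj)
  add(rows, rows, rep(1, length(rows)))

  ## continuity rows at every cell
  gi <- rep(seq_len(nx), times = ny)
  gj <- rep(seq_len(ny), each = nx)
  rows <- ip(gi, gj)
  add(rows, iu(gi, gj), rep(-1 / dx, length(rows)))
  add(rows, iu(gi + 1, gj), rep(1 / dx, length(rows)))
  add(rows, iv(gi, gj), rep(-1 / dy, length(rows)))
  add(rows, iv(gi, gj + 1), rep(1 / dy, length(rows)))

  N <- Nu + Nv + nx * ny
  Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                       dims = c(N, N))
}

#' Solve steady flow through the (partially lysed) occluded channel
#'
#' Steady volume-averaged momentum + continuity on a staggered grid with
#' Darcian clot resistance, fixed pressures at inlet and outlet, no-slip
#' walls, and an optional continuity source (the lysis-driven voidage change).
#' The linear Stokes-Brinkman operator is factorised once; convection is
#' converged by relaxed Picard iteration on the right-hand side.
#'
#' @param grid [buildChannel()] grid
#' @param permeability per-cell permeability (m2), nx x ny matrix (or scalar)
#' @param voidage per-cell voidage; cells at or above the lysed threshold
#'   lose their Darcy resistance entirely
#' @param dp pressure drop inlet minus outlet (Pa), >= 0
#' @param fluid [fluidProps()]
#' @param mp [microParams()] (for the lysed-voidage threshold)
#' @param mass_source per-cell continuity source (1/s): div u = mass_source.
#'   Lysis creates pore volume, so the caller passes -d(eps)/dt. Default 0.
#' @param warm_start optional previous `flow_field` used as Picard initial
#'   iterate
#' @param max_iter,tol Picard iteration cap and relative convergence tolerance
#' @param relax Picard relaxation factor
#' @param inertia include the convective term (set FALSE for pure
#'   Stokes-Brinkman)
#' @return object of class `flow_field`: `u` ((nx+1) x ny), `v` (nx x (ny+1)),
#'   `p` (nx x ny), iteration diagnostics
#' @export
solveFlow <- function(grid, permeability, voidage = NULL, dp,
                      fluid = fluidProps(), mp = microParams(),
                      mass_source = NULL, warm_start = NULL,
                      max_iter = 200, tol = 3e-4, relax = 0.7,
                      inertia = TRUE) {
  nx <- grid$nx; ny <- grid$ny
  if (dp < 0) stop("dp must be >= 0", call. = FALSE)
  if (length(permeability) == 1)
    permeability <- matrix(permeability, nx, ny)
  if (any(permeability <= 0)) stop("permeabilities must be > 0", call. = FALSE)
  resist <- matrix(0, nx, ny)
  inclot <- grid$clot_mask
  if (!is.null(voidage))
    inclot <- inclot & voidage < mp$voidage_lysed_threshold
  resist[inclot] <- fluid$viscosity / permeability[inclot]
  if (is.null(mass_source)) mass_source <- matrix(0, nx, ny)

  A <- assembleFlowMatrix(grid, resist, fluid)
  # row equilibration: Darcy-dominated momentum rows are ~1e11, continuity
  # rows ~1e4; scale rows to unit 1-norm so the sparse LU stays well posed
  rs <- 1 / Matrix::rowSums(abs(A))
  fac <- Matrix::lu(Matrix::Diagonal(x = rs) %*% A)
  Nu <- (nx + 1) * ny; Nv <- nx * (ny + 1)
  p_in <- dp; p_out <- 0

  u <- if (!is.null(warm_start)) warm_start$u else matrix(0, nx + 1, ny)
  v <- if (!is.null(warm_start)) warm_start$v else matrix(0, nx, ny + 1)
  resid <- numeric(0)
  for (it in seq_len(max_iter)) {
    conv <- if (inertia) convectionTerms(u, v, grid, fluid$density)
            else list(u = matrix(0, nx + 1, ny), v = matrix(0, nx, ny + 1))
    b <- numeric(Nu + Nv + nx * ny)
    bu <- conv$u
    bu[1, ] <- bu[1, ] - 2 * p_in / grid$dx
    bu[nx + 1, ] <- bu[nx + 1, ] + 2 * p_out / grid$dx
    b[seq_len(Nu)] <- as.vector(bu)
    bv <- conv$v
    vrhs <- matrix(0, nx, ny + 1)
    vrhs[, 2:ny] <- bv[, 2:ny]
    b[Nu + seq_len(Nv)] <- as.vector(vrhs)
    b[Nu + Nv + seq_len(nx * ny)] <- as.vector(mass_source)

    x <- as.numeric(Matrix::solve(fac, rs * b))
    u_new <- matrix(x[seq_len(Nu)], nx + 1, ny)
    v_new <- matrix(x[Nu + seq_len(Nv)], nx, ny + 1)
    p <- matrix(x[Nu + Nv + seq_len(nx * ny)], nx, ny)
    scale <- max(abs(u_new), abs(v_new), 1e-300)
    change <- max(abs(u_new - u), abs(v_new - v)) / scale
    resid <- c(resid, change)
    w <- if (it == 1) 1 else relax
    u <- w * u_new + (1 - w) * u
    v <- w * v_new + (1 - w) * v
    if (change < tol) break
  }
  if (utils::tail(resid, 1) >= tol && inertia && max_iter > 1)
    stop("flow solver failed to converge; residual history: ",
         paste(signif(resid, 3), collapse = " "), call. = FALSE)
  structure(list(u = u, v = v, p = p, iterations = length(resid),
                 resid = resid, dp = dp, grid = grid),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> dp = %g Pa, max |u| = %.3g m/s, %d Picard iterations\n",
              x$dp, max(abs(x$u)), x$iterations))
  invisible(x)
}

#' Discrete divergence of a flow field
#'
#' @param f [solveFlow()] result
#' @param grid [buildChannel()] grid
#' @return nx x ny matrix of per-cell divergence (1/s)
#' @export
flowDivergence <- function(f, grid) {
  nx <- grid$nx; ny <- grid$ny
  (f$u[2:(nx + 1), , drop = FALSE] - f$u[1:nx, , drop = FALSE]) / grid$dx +
    (f$v[, 2:(ny + 1), drop = FALSE] - f$v[, 1:ny, drop = FALSE]) / grid$dy
}

# bilinear interpolation of the cell-centred velocity
interpVelocity <- function(f, grid, x, y) {
  nx <- grid$nx; ny <- grid$ny
  uc <- 0.5 * (f$u[1:nx, , drop = FALSE] + f$u[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (f$v[, 1:ny, drop = FALSE] + f$v[, 2:(ny + 1), drop = FALSE])
  gx <- pmin(pmax(x / grid$dx + 0.5, 1), nx)
  gy <- pmin(pmax(y / grid$dy + 0.5, 1), ny)
  i0 <- pmin(floor(gx), nx - 1); j0 <- pmin(floor(gy), ny - 1)
  fx <- gx - i0; fy <- gy - j0
  bil <- function(M)
    M[cbind(i0, j0)] * (1 - fx) * (1 - fy) + M[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    M[cbind(i0, j0 + 1)] * (1 - fx) * fy + M[cbind(i0 + 1, j0 + 1)] * fx * fy
  list(u = bil(uc), v = bil(vc))
}

#' Trace velocity streamlines
#'
#' Fixed-step 4th-order Runge-Kutta integration of the velocity field from
#' seed points; used to visualise recirculation zones. Seeds outside the
#' domain are skipped with a warning.
#'
#' @param f [solveFlow()] result
#' @param grid grid
#' @param seeds data.frame or matrix with columns x, y (m)
#' @param step integration step as a fraction of dx
#' @param max_steps cap on steps per line
#' @return list of data.frames (x, y), one per seed
#' @export
computeStreamlines <- function(f, grid, seeds, step = 0.5, max_steps = 4000) {
  seeds <- as.matrix(seeds)
  out <- list()
  umax <- max(abs(f$u), abs(f$v), 1e-300)
  h <- step * grid$dx / umax
  for (s in seq_len(nrow(seeds))) {
    x <- seeds[s, 1]; y <- seeds[s, 2]
    if (x < 0 || x > grid$length || y < 0 || y > grid$height) {
      warning("seed ", s, " outside domain; skipped")
      next
    }
    px <- numeric(max_steps); py <- numeric(max_steps)
    n <- 0
    for (k in seq_len(max_steps)) {
      n <- n + 1; px[n] <- x; py[n] <- y
      k1 <- interpVelocity(f, grid, x, y)
      k2 <- interpVelocity(f, grid, x + h / 2 * k1$u, y + h / 2 * k1$v)
      k3 <- interpVelocity(f, grid, x + h / 2 * k2$u, y + h / 2 * k2$v)
      k4 <- interpVelocity(f, grid, x + h * k3$u, y + h * k3$v)
      x <- x + h / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
      y <- y + h / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
      if (x < 0 || x > grid$length || y < 0 || y > grid$height) break
    }
    out[[s]] <- data.frame(x = px[seq_len(n)], y = py[seq_len(n)])
  }
  out
}

#' Recirculation metrics distal to the clot
#'
#' Area of reversed streamwise flow (cell-centred u < 0) downstream of the
#' initial clot, split into the half-channels above and below the centreline,
#' with the normalised top/bottom asymmetry.
#'
#' @param f [solveFlow()] result
#' @param grid grid
#' @param clot_mask initial clot mask (nx x ny); defaults to the grid's
#' @return list: `area_top`, `area_bottom` (m2), `asymmetry`
#' @export
recirculationMetrics <- function(f, grid, clot_mask = grid$clot_mask) {
  nx <- grid$nx; ny <- grid$ny
  uc <- 0.5 * (f$u[1:nx, , drop = FALSE] + f$u[2:(nx + 1), , drop = FALSE])
  distal_cols <- grid$xc > max(c(grid$xc[rowSums(clot_mask) > 0], -Inf))
  rev_flow <- uc < 0 & matrix(distal_cols, nx, ny)
  top <- matrix(rep(grid$yc > grid$height / 2, each = nx), nx, ny)
  cell <- grid$dx * grid$dy
  a_top <- sum(rev_flow & top) * cell
  a_bot <- sum(rev_flow & !top) * cell
  asym <- if (a_top + a_bot > 0) abs(a_top - a_bot) / (a_top + a_bot) else 0
  list(area_top = a_top, area_bottom = a_bot, asymmetry = asym)
}
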