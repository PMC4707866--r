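test_that("quiescent transport with inert kinetics leaves the fields unchanged", {
  g <- smallChannel()
  N <- g$nx * g$ny
  fields <- list(G = matrix(runif(3 * N), 3, N, dimnames = list(c("tPA", "PLG", "PLS"), NULL)),
                 S = matrix(0, 3, N), L = numeric(N))
  f0 <- uniformFlow(g, 0)
  out <- transportStep2D(fields, f0, g, dt = 1, kp = inertKP, mp = defaultMP,
                         inlet = c(tPA = 0, PLG = 0, PLS = 0), D = 0,
                         kin_dt = Inf)
  expect_equal(out$G, fields$G, tolerance = 1e-12)
})

test_that("a uniform concentration is preserved by divergence-free advection", {
  g <- smallChannel()
  fl <- fluidProps()
  flow <- solveFlow(g, permeability = 1e-6,
                    voidage = matrix(1, g$nx, g$ny), dp = 0.1,
                    fluid = fl, mp = defaultMP)
  N <- g$nx * g$ny
  C0 <- 0.04
  fields <- list(G = matrix(C0, 3, N, dimnames = list(c("tPA", "PLG", "PLS"), NULL)),
                 S = matrix(0, 3, N), L = numeric(N))
  # fully fluid domain (eps = 1): mask carries no clot kinetics
  gg <- g; gg$clot_mask <- matrix(FALSE, g$nx, g$ny)
  out <- fields
  for (i in 1:20)
    out <- transportStep2D(out, flow, gg, dt = 0.05, kp = inertKP,
                           mp = defaultMP,
                           inlet = c(tPA = C0, PLG = C0, PLS = C0),
                           D = 5e-11, kin_dt = Inf)
  expect_lt(max(abs(out$G - C0)) / C0, 1e-6)
})

test_that("a passive tracer arrives on the plug-flow time scale", {
  g <- smallChannel(nx = 40, ny = 8)
  fl <- fluidProps()
  flow <- solveFlow(g, permeability = 1e-6,
                    voidage = matrix(1, g$nx, g$ny), dp = 0.5,
                    fluid = fl, mp = defaultMP)
  u_mean <- mean(0.5 * (flow$u[1:g$nx, ] + flow$u[2:(g$nx + 1), ]))
  gg <- g; gg$clot_mask <- matrix(FALSE, g$nx, g$ny)
  N <- g$nx * g$ny
  fields <- list(G = matrix(0, 3, N, dimnames = list(c("tPA", "PLG", "PLS"), NULL)),
                 S = matrix(0, 3, N), L = numeric(N))
  t_plug <- g$length / u_mean
  dt <- t_plug / 400
  t <- 0; arrived <- NA
  for (i in 1:2000) {
    fields <- transportStep2D(fields, flow, gg, dt, kp = inertKP,
                              mp = defaultMP,
                              inlet = c(tPA = 1, PLG = 0, PLS = 0),
                              D = 1e-11, kin_dt = Inf)
    t <- t + dt
    outlet_mean <- mean(fields$G["tPA", (seq_len(g$ny) - 1) * g$nx + g$nx])
    if (outlet_mean >= 0.5) { arrived <- t; break }
  }
  # upwind diffusion smears the front: demand the right time scale, not the
  # exact plug-flow arrival
  expect_false(is.na(arrived))
  expect_gt(arrived, 0.4 * t_plug)
  expect_lt(arrived, 1.6 * t_plug)
})

test_that("breakthrough ratio is linear for fabricated linear lysis growth", {
  g <- smallChannel()
  times <- seq(0, 100, by = 10)
  # lysed fraction grows linearly in time, uniformly over the clot
  fracs <- lapply(times, function(t) {
    Fm <- matrix(0, g$nx, g$ny)
    Fm[g$clot_mask] <- t / 100
    Fm
  })
  h <- list(time = times, frac = fracs, grid = g,
            exit_col = max(which(rowSums(g$clot_mask) > 0)))
  btr <- breakthroughRatio(h)
  # 1% first reached at t = 10 (frac 0.1), 95% at t = 100
  expect_equal(attr(btr, "t_start"), 10)
  expect_equal(attr(btr, "t_breakthrough"), 100)
  sel <- !is.na(btr$btr)
  expect_equal(btr$btr[sel], (times[sel] - 10) / 90)
  expect_equal(btr$btr[btr$time == 100], 1.0)
  expect_equal(btr$btr[btr$time == 10], 0.0)
  # no breakthrough: all NA
  h$frac <- lapply(times, function(t) matrix(0, g$nx, g$ny))
  expect_true(all(is.na(breakthroughRatio(h)$btr)))
})

test_that("zero inlet tPA leaves the occlusion intact", {
  g <- scaledChannel()
  r <- simulateOcclusionLysis(g, dp = 1,
                              inlet = c(tPA = 0, PLG = 2, PLS = 0),
                              t_end = 120, metric_dt = 30)
  expect_equal(max(r$history$frac[[length(r$history$frac)]]), 0)
  expect_true(is.na(r$metrics$t_breakthrough))
  # flow across the intact occlusion is pure permeation: tiny but nonzero
  expect_gt(max(abs(r$metrics$final_flow$u)), 0)
  expect_lt(max(abs(r$metrics$final_flow$u)), 1e-5)
})

test_that("single-entry pressure sweep reduces to one simulation", {
  g <- scaledChannel()
  tab <- comparePressureDrops(5, grid = g, t_end = 2000, stop_btr = 1.25,
                              metric_dt = 20)
  expect_equal(nrow(tab), 1)
  r <- simulateOcclusionLysis(g, dp = 5, t_end = 2000, stop_btr = 1.25,
                              metric_dt = 20)
  expect_equal(tab$t_breakthrough, r$metrics$t_breakthrough)
  expect_error(comparePressureDrops(numeric(0)), "empty")
})
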