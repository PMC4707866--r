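test_that("adsorption rate has the Langmuir form and vanishes at equilibrium", {
  kp <- defaultKP
  expect_equal(adsorptionRate(0, 0, 10, 0, kp, "tPA"), 0)
  # saturated sites, nothing bound of this species: no flux either way
  expect_equal(adsorptionRate(1, 0, 10, 10, kp, "PLG"), 0)
  # algebraic steady state of the adsorption ODE: S/(C*(theta-S)) = Kd^-1
  Kd <- kp$k_rev[["PLG"]] / kp$k_ads[["PLG"]]
  C <- 1.2; theta <- 50
  S_eq <- theta * C / (Kd + C)
  expect_equal(adsorptionRate(C, S_eq, theta, S_eq, kp, "PLG"), 0,
               tolerance = 1e-10)
  expect_error(adsorptionRate(-1, 0, 10, 0, kp, "tPA"), ">= 0")
  expect_error(adsorptionRate(1, 0, 10, 11, kp, "tPA"), "exceed")
})

test_that("plasmin generation follows Michaelis-Menten in the bound phase", {
  kp <- defaultKP
  expect_equal(plasminGenerationRate(0.3, 0, kp), 0)
  expect_equal(plasminGenerationRate(0.3, kp$K_M, kp), kp$k2 * 0.3 / 2)
  expect_equal(plasminGenerationRate(0.3, 1e9, kp), kp$k2 * 0.3,
               tolerance = 1e-6)
})

test_that("antiplasmin inhibition is second order and conserves plasmin + complex", {
  kp <- defaultKP
  expect_equal(plasminInhibitionRate(0.5, 0, kp), 0)
  expect_equal(plasminInhibitionRate(0, 1, kp), 0)
  # one explicit Euler step: PLS + complex total unchanged, AP consumed 1:1
  C_PLS <- 0.4; C_AP <- 0.8; dt <- 1e-3
  r <- plasminInhibitionRate(C_PLS, C_AP, kp)
  expect_equal((C_PLS - dt * r) + (0 + dt * r), C_PLS)
  expect_equal((C_AP - dt * r) - C_AP, -(dt * r))
})

test_that("lysis rate is linear in bound plasmin and stops at complete lysis", {
  kp <- defaultKP; n0 <- defaultMP$n0_uM
  expect_equal(lysisRate(0, 0.1, n0, kp), 0)
  expect_equal(lysisRate(5, n0, n0, kp), 0)
  expect_equal(lysisRate(2, 0.1, n0, kp), 2 * lysisRate(1, 0.1, n0, kp))
})

test_that("solubilization fluxes scale with bound mass and lysis rate", {
  kp <- defaultKP; n0 <- defaultMP$n0_uM
  S <- c(tPA = 0.2, PLG = 10, PLS = 1)
  expect_equal(solubilizationRates(S, 0.1, 0, n0, kp), S * 0)
  expect_equal(solubilizationRates(c(tPA = 0, PLG = 0, PLS = 0), 0.1, 0.01,
                                   n0, kp),
               c(tPA = 0, PLG = 0, PLS = 0))
  rate <- solubilizationRates(S, n0 / 2, 0.01, n0, kp)
  expect_equal(unname(rate), unname(kp$kappa * S * 0.01 / (n0 / 2)))
})

test_that("pooled free + bound inventory is conserved by adsorption alone", {
  # lysis, generation and inhibition off: adsorption/desorption only
  kp <- kineticParams(k2 = 0, k_cat = 0, k_AP = 0)
  h <- simulateWellMixed(kp, defaultMP,
                         C0 = c(tPA = 0.05, PLG = 2, PLS = 0.01, AP = 0),
                         S0 = c(tPA = 0, PLG = 0, PLS = 0), t_end = 400)
  pool <- kp$plasma_volume_ratio + h$voidage
  for (sp in c("tPA", "PLG", "PLS")) {
    tot <- pool * h[[paste0("C_", sp)]] + h[[paste0("S_", sp)]]
    expect_lt(diff(range(tot)) / tot[1], 1e-6)
  }
  # the closed clot-only limit (no plasma pool) conserves eps*C + S
  kp0 <- kineticParams(k2 = 0, k_cat = 0, k_AP = 0, plasma_volume_ratio = 0)
  h0 <- simulateWellMixed(kp0, defaultMP,
                          C0 = c(tPA = 0.05, PLG = 2, PLS = 0, AP = 0),
                          S0 = c(tPA = 0, PLG = 0, PLS = 0), t_end = 400)
  tot0 <- h0$voidage * h0$C_PLG + h0$S_PLG
  expect_lt(diff(range(tot0)) / tot0[1], 1e-6)
})

test_that("without tPA the clot never lyses", {
  init <- referenceWellMixedInit(defaultKP, defaultMP, tPA_uM = 0)
  h <- simulateWellMixed(defaultKP, defaultMP, C0 = init$C0, S0 = init$S0,
                         t_end = 200)
  expect_equal(max(h$frac_lysed), 0)
  expect_equal(max(h$C_PLS), 0)
})

test_that("all-zero state has all-zero derivatives", {
  y0 <- c(F_tPA = 0, F_PLG = 0, F_PLS = 0, F_AP = 0, F_APPLS = 0,
          S_tPA = 0, S_PLG = 0, S_PLS = 0, L = 0)
  dy <- rhsWellMixed(0, y0, list(kp = defaultKP, mp = defaultMP))[[1]]
  expect_equal(unname(dy), rep(0, 9))
})

test_that("reference lysis run is monotone, complete, and empties the bound phase", {
  init <- referenceWellMixedInit(defaultKP, defaultMP)
  h <- simulateWellMixed(defaultKP, defaultMP, C0 = init$C0, S0 = init$S0,
                         t_end = 150)
  expect_true(all(diff(h$frac_lysed) > -1e-12))
  expect_gt(max(h$frac_lysed), 0.999)
  # the bound phases ride the vanishing binding-site budget down to zero:
  # solubilization keeps S proportional to the remaining fibrin, so at 99.9%
  # lysis less than a thousandth of the bound protein remains
  end <- h[nrow(h), ]
  expect_lt(end$S_PLG + end$S_PLS + end$S_tPA, 1e-3 * 34.9)
  thp <- defaultMP$theta0_uM[["PLG"]] * (1 - h$frac_lysed)
  expect_true(all(h$S_PLG + h$S_PLS <= thp + 1e-3 * defaultMP$theta0_uM[["PLG"]]))
  # permeability has climbed orders of magnitude toward the lysed-clot cap
  k0 <- initialClotState(defaultMP)$permeability
  expect_gt(end$permeability / k0, 10)
  expect_true(all(diff(h$permeability) >= 0))
})

test_that("halving solver tolerances moves the lysis time by less than 1%", {
  init <- referenceWellMixedInit(defaultKP, defaultMP)
  t1 <- timeToLysis(simulateWellMixed(defaultKP, defaultMP, init$C0, init$S0,
                                      t_end = 150, rtol = 1e-6, atol = 1e-8),
                    0.99)
  t2 <- timeToLysis(simulateWellMixed(defaultKP, defaultMP, init$C0, init$S0,
                                      t_end = 150, rtol = 5e-7, atol = 4e-9),
                    0.99)
  expect_lt(abs(t1 - t2) / t1, 0.01)
})

test_that("plasminogen equilibration reduces to the trivial limits", {
  kp0 <- kineticParams(k_ads = c(tPA = 0.1, PLG = 0, PLS = 0.1))
  eq <- equilibratePlg(kp0, defaultMP, 2)
  expect_equal(eq$free, 2)
  expect_equal(eq$bound, 0)
  expect_error(equilibratePlg(defaultKP, defaultMP, 0), "> 0")
})

test_that("time to lysis interpolates between snapshots", {
  h <- data.frame(time = c(0, 10, 20, 30),
                  frac_lysed = c(0, 0.2, 0.6, 1.0))
  expect_equal(timeToLysis(h, 0.4), 15)
  expect_equal(timeToLysis(h, 0.95), 28.75)
  expect_true(is.na(timeToLysis(h[1:2, ], 0.5)))
  expect_error(timeToLysis(h, 0), "0, 1")
  expect_error(timeToLysis(h, 1.2), "0, 1")
  expect_gte(timeToLysis(h, 1), timeToLysis(h, 0.95))
})

test_that("lysis time falls monotonically with tPA dose in the assay configuration", {
  # assay conditions: 2 mg/ml fibrin (5.88 uM), K_M 2.42 uM, k2 0.22 1/s
  kp <- kineticParams(k2 = 0.22, K_M = 2.42)
  mp <- microParams(fibrin_density_mg_ml = 2)
  tab <- doseResponseWellMixed(c(0.001, 0.01, 0.05, 0.1), kp, mp,
                               fraction = 0.95, t_end = 30000)
  expect_true(all(is.finite(tab$t_lysis_s)))
  expect_true(all(diff(tab$t_lysis_s) < 0))
})
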