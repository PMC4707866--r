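# Shared fixtures: default parameter sets and small grids built in code.

defaultMP <- microParams()
defaultKP <- kineticParams()

# kinetics fully switched off (binding, generation, lysis, inhibition)
inertKP <- kineticParams(k_ads = c(tPA = 0, PLG = 0, PLS = 0),
                         k_rev = c(tPA = 0, PLG = 0, PLS = 0),
                         k2 = 0, k_cat = 0, k_AP = 0)

# compact full-height channel for flow unit tests (clot resolved by >13 cells)
testChannel <- function(nx = 80, ny = 24)
  buildChannel(height_m = 5e-3, clot_width_m = 2.5e-3, upstream_m = 5e-3,
               downstream_m = 7.5e-3, nx = nx, ny = ny)

# small 2D channel used by the coupled-tier unit tests
smallChannel <- function(nx = 40, ny = 8)
  buildChannel(height_m = 1e-3, clot_width_m = 5e-4, upstream_m = 5e-4,
               downstream_m = 1e-3, nx = nx, ny = ny)

# scaled occlusion channel shared by coupled tests and acceptance
scaledChannel <- function()
  buildChannel(height_m = 1e-3, clot_width_m = 5e-4, upstream_m = 1e-3,
               downstream_m = 2.5e-3, nx = 80, ny = 20)

# a hand-made uniform flow field (u constant, v zero) on a grid
uniformFlow <- function(grid, u0) {
  structure(list(u = matrix(u0, grid$nx + 1, grid$ny),
                 v = matrix(0, grid$nx, grid$ny + 1),
                 p = matrix(0, grid$nx, grid$ny),
                 dp = NA, grid = grid),
            class = "flow_field")
}
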