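test_that("scenario validation rejects unknown keys, bad tiers and bad units", {
  ok <- list(tier = "well_mixed")
  expect_silent(validateScenario(ok))
  expect_error(validateScenario(list(tier = "well_mixed", bogus = 1)),
               "bogus")
  expect_error(validateScenario(list(tier = "well_mixed",
                                     kinetics = list(k2 = 1))),
               "kinetics\\$k2")
  expect_error(validateScenario(list(tier = "everything")), "tier must be")
  expect_error(validateScenario(list(tier = "coupled2d",
                                     conditions = list(pressure_drop_Pa = -1))),
               "Pa")
})

test_that("config save and load round-trips and fills defaults", {
  sc <- referenceScenarios()[["well-mixed"]]
  p <- withr::local_tempfile(fileext = ".yaml")
  saveScenario(sc, p)
  expect_identical(loadScenario(p), sc)
  # minimal config gets the study defaults: 50 nM tPA, 2 uM PLG
  p2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("tier: well_mixed", p2)
  cfg <- loadScenario(p2)
  expect_equal(cfg$conditions$tPA_nM, 50)
  expect_equal(cfg$conditions$PLG_uM, 2)
  expect_error(loadScenario("/nonexistent/x.yaml"), "not found")
})

test_that("every shipped scenario passes validation with the study conditions", {
  sc <- referenceScenarios()
  expect_gt(length(sc), 8)
  for (s in sc) expect_silent(validateScenario(s))
  v <- sc[["well-mixed-validation"]]
  expect_equal(v$kinetics$K_M_uM, 2.42)
  expect_equal(v$kinetics$k2_per_s, 0.22)
  expect_equal(clotlysis:::scenarioParams(v)$mp$n0_uM, 5.882353,
               tolerance = 1e-6)
  o <- sc[["occlusion-1Pa"]]
  expect_equal(o$geometry2d$height_mm, 5)
  expect_equal(o$geometry2d$clot_width_mm, 2.5)
  expect_equal(o$conditions$pressure_drop_Pa, 1)
})

test_that("outputs are deterministic and empty histories yield a manifest only", {
  run <- runScenario(referenceScenarios()[["well-mixed"]])
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- writeOutputs(run, d1)
  f2 <- writeOutputs(run, d2)
  expect_true(any(grepl("history.csv", f1)))
  expect_true(any(grepl("manifest.json", f1)))
  h1 <- f1[grepl("history.csv", f1)]; h2 <- f2[grepl("history.csv", f2)]
  expect_identical(readLines(h1), readLines(h2))
  mf <- jsonlite::read_json(f1[grepl("manifest", f1)])
  expect_equal(mf$tier, "well_mixed")
  expect_true(is.numeric(mf$metrics$time_to_0.99_lysis_s))

  empty <- list(config = list(name = "void", tier = "well_mixed",
                              output = list(formats = "csv")),
                tier = "well_mixed",
                result = list(history = data.frame()),
                summary = NULL, wall_time_s = 0)
  d3 <- withr::local_tempdir()
  expect_warning(files <- writeOutputs(empty, d3), "manifest only")
  expect_length(files, 1)
  expect_match(files, "manifest.json")
})

test_that("2D snapshot sets produce one VTK file per snapshot", {
  g <- smallChannel()
  snaps <- list(
    snap0.50 = list(btr = 0.5, time = 10, frac = matrix(0.1, g$nx, g$ny)),
    snap1.00 = list(btr = 1.0, time = 20, frac = matrix(0.5, g$nx, g$ny)))
  h <- structure(list(time = c(0, 10, 20),
                      frac = list(matrix(0, g$nx, g$ny),
                                  snaps[[1]]$frac, snaps[[2]]$frac),
                      grid = g, exit_col = 20, snapshots = snaps),
                 class = "lysis_history")
  run <- list(config = list(name = "vtk-check", tier = "coupled2d",
                            output = list(formats = "vtk")),
              tier = "coupled2d", result = list(history = h),
              summary = NULL, wall_time_s = 0)
  d <- withr::local_tempdir()
  files <- writeOutputs(run, d)
  expect_equal(sum(grepl("\\.vtk$", files)), length(snaps))
  v <- readLines(files[grepl("btr0.50", files)])
  expect_equal(v[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("DIMENSIONS 40 8 1", v)))
})

test_that("the CLI validates, lists, runs, and signals config errors", {
  sc <- referenceScenarios()[["well-mixed"]]
  p <- withr::local_tempfile(fileext = ".yaml")
  saveScenario(sc, p)
  expect_equal(runCli(c("validate", p)), 0L)
  expect_output(expect_equal(runCli("list-scenarios"), 0L), "well-mixed")
  expect_equal(suppressMessages(runCli(c("run", "/missing.yaml"))), 2L)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("tier: well_mixed", "bogus: 1"), bad)
  expect_equal(suppressMessages(runCli(c("validate", bad))), 2L)
  d <- withr::local_tempdir()
  expect_message(code <- runCli(c("run", p, "--out", d, "--seed", "7")),
                 "wrote")
  expect_equal(code, 0L)
  expect_true(any(grepl("manifest", list.files(d))))
})
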