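# Scenario configuration, reference scenarios, output writers and the
# command-line front end. Configs are plain YAML with explicit unit suffixes
# in key names (the model mixes nm/mm/uM/Pa, and silent unit slips are the
# dominant failure mode); unknown keys are rejected.

scenarioSchema <- list(
  top = c("name", "tier", "kinetics", "microstructure", "fluid",
          "conditions", "geometry1d", "geometry2d", "numerics", "output"),
  tier = c("well_mixed", "well_mixed_dose_response", "transport1d",
           "dose_sweep_1d", "coupled2d", "pressure_sweep"),
  kinetics = c("k_ads_per_uM_s", "k_rev_per_s", "k2_per_s", "K_M_uM",
               "k_cat_per_s", "gamma", "kappa", "k_AP_per_uM_s",
               "k_loss_per_s", "plasma_volume_ratio"),
  microstructure = c("fibrin_density_mg_ml", "fibre_radius_nm",
                     "monomer_mass_g_mol", "fibre_fibrin_mg_ml",
                     "binding_sites_per_monomer", "k_max_m2",
                     "voidage_lysed_threshold", "theta_exponent"),
  fluid = c("density_kg_m3", "viscosity_Pa_s"),
  conditions = c("tPA_nM", "PLG_uM", "AP_uM", "D_m2_s", "pressure_drop_Pa",
                 "doses_nM", "pressure_drops_Pa"),
  geometry1d = c("length_mm", "n_cells", "clot_start_mm", "clot_end_mm"),
  geometry2d = c("height_mm", "clot_width_mm", "upstream_mm", "downstream_mm",
                 "nx", "ny"),
  numerics = c("t_end_s", "rtol", "atol", "dt_safety", "kin_dt_s", "dt_max_s",
               "cfl", "metric_dt_s", "stop_btr", "lysis_fraction",
               "snapshot_times_s"),
  output = c("dir", "formats", "seed_recorded")
)

#' Validate a scenario configuration
#'
#' Checks section and key names against the schema and the physical sanity of
#' the values; errors list every offending key at once.
#'
#' @param config scenario list (as parsed from YAML)
#' @return the config, invisibly, if valid
#' @export
validateScenario <- function(config) {
  bad <- character(0)
  bad <- c(bad, setdiff(names(config), scenarioSchema$top))
  for (sec in intersect(names(config), names(scenarioSchema))) {
    if (sec %in% c("top", "tier")) next
    bad <- c(bad, paste0(sec, "$",
                         setdiff(names(config[[sec]]), scenarioSchema[[sec]])))
  }
  bad <- bad[!grepl("\\$$", bad)]
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(config$tier) || !config$tier %in% scenarioSchema$tier)
    stop("tier must be one of: ", paste(scenarioSchema$tier, collapse = ", "),
         call. = FALSE)
  cnd <- config$conditions
  if (!is.null(cnd$pressure_drop_Pa) && cnd$pressure_drop_Pa < 0)
    stop("conditions$pressure_drop_Pa must be >= 0 (Pa)", call. = FALSE)
  if (!is.null(cnd$tPA_nM) && cnd$tPA_nM < 0)
    stop("conditions$tPA_nM must be >= 0 (nM)", call. = FALSE)
  for (key in c("PLG_uM", "AP_uM", "D_m2_s"))
    if (!is.null(cnd[[key]]) && cnd[[key]] < 0)
      stop("conditions$", key, " must be >= 0", call. = FALSE)
  invisible(config)
}

#' Load a scenario configuration from YAML
#'
#' Parses, validates and fills defaults: the result always carries the full
#' tier, conditions and output sections (50 nM tPA and 2 uM PLG at the inlet
#' unless overridden).
#'
#' @param path YAML file
#' @return validated scenario list
#' @export
loadScenario <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  config <- yaml::read_yaml(path)
  validateScenario(config)
  applyScenarioDefaults(config)
}

applyScenarioDefaults <- function(config) {
  dflt <- list(tPA_nM = 50, PLG_uM = 2, AP_uM = 1, D_m2_s = 5e-11)
  for (k in names(dflt))
    if (is.null(config$conditions[[k]])) config$conditions[[k]] <- dflt[[k]]
  if (is.null(config$output$formats)) config$output$formats <- c("csv", "json")
  if (is.null(config$name)) config$name <- "unnamed"
  config
}

#' Save a scenario configuration to YAML
#'
#' @param config scenario list
#' @param path output file
#' @return path, invisibly
#' @export
saveScenario <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# build parameter objects from a scenario
scenarioParams <- function(config) {
  ka <- formals(kineticParams); ma <- formals(microParams)
  kin <- config$kinetics
  kargs <- list()
  map <- c(k_ads_per_uM_s = "k_ads", k_rev_per_s = "k_rev", k2_per_s = "k2",
           K_M_uM = "K_M", k_cat_per_s = "k_cat", gamma = "gamma",
           kappa = "kappa", k_AP_per_uM_s = "k_AP", k_loss_per_s = "k_loss",
           plasma_volume_ratio = "plasma_volume_ratio")
  for (k in names(kin)) {
    v <- kin[[k]]
    if (k %in% c("k_ads_per_uM_s", "k_rev_per_s")) v <- unlist(v)
    kargs[[map[[k]]]] <- v
  }
  mmap <- c(fibrin_density_mg_ml = "fibrin_density_mg_ml",
            fibre_radius_nm = "fibre_radius_nm",
            monomer_mass_g_mol = "monomer_mass_g_mol",
            fibre_fibrin_mg_ml = "fibre_fibrin_mg_ml",
            binding_sites_per_monomer = "binding_sites_per_monomer",
            k_max_m2 = "k_max_m2",
            voidage_lysed_threshold = "voidage_lysed_threshold",
            theta_exponent = "theta_exponent")
  margs <- list()
  for (k in names(config$microstructure)) {
    v <- config$microstructure[[k]]
    if (k == "binding_sites_per_monomer") v <- unlist(v)
    margs[[mmap[[k]]]] <- v
  }
  fargs <- list()
  if (!is.null(config$fluid$density_kg_m3))
    fargs$density_kg_m3 <- config$fluid$density_kg_m3
  if (!is.null(config$fluid$viscosity_Pa_s))
    fargs$viscosity_Pa_s <- config$fluid$viscosity_Pa_s
  list(kp = do.call(kineticParams, kargs),
       mp = do.call(microParams, margs),
       fluid = do.call(fluidProps, fargs))
}

#' Shipped reference scenarios
#'
#' The named scenario set covering every tier: the reference well-mixed run
#' (plasminogen-equilibrated clot + 50 nM tPA), the well-mixed dose-response
#' validation variant (fibrin 2 mg/ml = 5.88 uM, K_M 2.42 uM, k2 0.22 1/s,
#' matching the assay conditions the kinetics were validated against), the 1D
#' lysis-front scenario, the 1D dose sweep, occlusion scenarios at 1-20 Pa in
#' the full channel geometry (5 mm height, 2.5 mm clot), and geometrically
#' scaled occlusion variants (1 mm channel, 0.5 mm clot) sized for quick runs
#' and the test suite.
#'
#' @return named list of validated scenario configs
#' @export
referenceScenarios <- function() {
  base2d <- list(height_mm = 5, clot_width_mm = 2.5, upstream_mm = 12.5,
                 downstream_mm = 25, nx = 160, ny = 40)
  scaled2d <- list(height_mm = 1, clot_width_mm = 0.5, upstream_mm = 1,
                   downstream_mm = 2.5, nx = 80, ny = 20)
  occl <- function(dp, geom, extra_name) {
    list(name = paste0("occlusion-", extra_name, dp, "Pa"), tier = "coupled2d",
         conditions = list(pressure_drop_Pa = dp),
         geometry2d = geom,
         numerics = list(t_end_s = 40000, stop_btr = 1.55, metric_dt_s = 10))
  }
  sc <- c(
    list(
      `well-mixed` = list(
        name = "well-mixed", tier = "well_mixed",
        numerics = list(t_end_s = 150, lysis_fraction = 0.99)),
      `well-mixed-validation` = list(
        name = "well-mixed-validation", tier = "well_mixed_dose_response",
        kinetics = list(k2_per_s = 0.22, K_M_uM = 2.42),
        microstructure = list(fibrin_density_mg_ml = 2),
        conditions = list(doses_nM = c(1, 5, 10, 50, 100)),
        numerics = list(t_end_s = 20000, lysis_fraction = 0.95)),
      `lysis-front-1d` = list(
        name = "lysis-front-1d", tier = "transport1d",
        geometry1d = list(length_mm = 3.6, n_cells = 180,
                          clot_start_mm = 0.1, clot_end_mm = 3.1),
        numerics = list(t_end_s = 5400,
                        snapshot_times_s = c(10, 30, 50, 70, 90) * 60)),
      `dose-sweep-1d` = list(
        name = "dose-sweep-1d", tier = "dose_sweep_1d",
        conditions = list(doses_nM = c(1, 10, 100, 1000)),
        geometry1d = list(length_mm = 3.6, n_cells = 180,
                          clot_start_mm = 0.1, clot_end_mm = 3.1),
        numerics = list(t_end_s = 5400)),
      `pressure-sweep-scaled` = list(
        name = "pressure-sweep-scaled", tier = "pressure_sweep",
        conditions = list(pressure_drops_Pa = c(1, 5, 10, 20)),
        geometry2d = scaled2d,
        numerics = list(t_end_s = 40000, stop_btr = 1.55, metric_dt_s = 10))
    ),
    stats::setNames(
      lapply(c(1, 5, 10, 20), occl, geom = base2d, extra_name = ""),
      paste0("occlusion-", c(1, 5, 10, 20), "Pa")),
    stats::setNames(
      lapply(c(1, 5, 10, 20), occl, geom = scaled2d, extra_name = "scaled-"),
      paste0("occlusion-scaled-", c(1, 5, 10, 20), "Pa"))
  )
  lapply(sc, function(s) applyScenarioDefaults(validateScenario(s)))
}

scenarioGrid1D <- function(config) {
  g <- config$geometry1d
  if (is.null(g)) return(grid1D())
  grid1D(length_m = g$length_mm * 1e-3, n_cells = g$n_cells,
         clot_start_m = g$clot_start_mm * 1e-3,
         clot_end_m = g$clot_end_mm * 1e-3)
}

scenarioGrid2D <- function(config) {
  g <- config$geometry2d
  if (is.null(g)) return(buildChannel())
  buildChannel(height_m = g$height_mm * 1e-3,
               clot_width_m = g$clot_width_mm * 1e-3,
               upstream_m = g$upstream_mm * 1e-3,
               downstream_m = g$downstream_mm * 1e-3,
               nx = g$nx, ny = g$ny)
}

#' Run a scenario
#'
#' Dispatches a validated scenario config to the matching simulation tier and
#' returns its result together with a one-row summary of the headline
#' metrics.
#'
#' @param config scenario list (see [loadScenario()], [referenceScenarios()])
#' @param verbose print progress for the 2D tiers
#' @return list with `config`, `tier`, `result`, `summary` (data.frame),
#'   `wall_time_s`
#' @export
runScenario <- function(config, verbose = FALSE) {
  validateScenario(config)
  config <- applyScenarioDefaults(config)
  pr <- scenarioParams(config)
  num <- config$numerics
  cnd <- config$conditions
  t0 <- proc.time()[[3]]
  inlet <- c(tPA = cnd$tPA_nM * 1e-3, PLG = cnd$PLG_uM, PLS = 0)
  res <- switch(
    config$tier,
    well_mixed = {
      init <- referenceWellMixedInit(pr$kp, pr$mp, tPA_uM = inlet[["tPA"]],
                                     PLG_total_uM = cnd$PLG_uM,
                                     AP_uM = cnd$AP_uM)
      h <- simulateWellMixed(pr$kp, pr$mp, C0 = init$C0, S0 = init$S0,
                             t_end = num$t_end_s %||% 150)
      fr <- num$lysis_fraction %||% 0.99
      list(history = h,
           summary = data.frame(metric = paste0("time_to_", fr, "_lysis_s"),
                                value = timeToLysis(h, fr)))
    },
    well_mixed_dose_response = {
      tab <- doseResponseWellMixed(cnd$doses_nM * 1e-3, pr$kp, pr$mp,
                                   fraction = num$lysis_fraction %||% 0.95,
                                   t_end = num$t_end_s %||% 20000)
      list(history = tab,
           summary = data.frame(metric = paste0("t95_dose", tab$dose_uM, "uM"),
                                value = tab$t_lysis_s))
    },
    transport1d = {
      h <- simulate1D(grid = scenarioGrid1D(config), kp = pr$kp, mp = pr$mp,
                      inlet = inlet,
                      D = stats::setNames(rep(cnd$D_m2_s, 3), SPECIES),
                      t_end = num$t_end_s %||% 5400,
                      snapshot_times = num$snapshot_times_s %||%
                        (c(10, 30, 50, 70, 90) * 60))
      list(history = h,
           summary = data.frame(metric = "front_velocity_um_min",
                                value = frontVelocity(h)))
    },
    dose_sweep_1d = {
      tab <- doseSweep1D(cnd$doses_nM * 1e-3, grid = scenarioGrid1D(config),
                         kp = pr$kp, mp = pr$mp,
                         D = stats::setNames(rep(cnd$D_m2_s, 3), SPECIES),
                         t_end = num$t_end_s %||% 5400)
      list(history = tab,
           summary = data.frame(
             metric = paste0("velocity_dose", tab$dose_uM, "uM_um_min"),
             value = tab$velocity_um_min))
    },
    coupled2d = {
      r <- simulateOcclusionLysis(
        grid = scenarioGrid2D(config), kp = pr$kp, mp = pr$mp,
        fluid = pr$fluid, dp = cnd$pressure_drop_Pa %||% 1, inlet = inlet,
        D = cnd$D_m2_s, t_end = num$t_end_s %||% 40000,
        stop_btr = num$stop_btr %||% Inf,
        metric_dt = num$metric_dt_s %||% 10, verbose = verbose)
      list(history = r$history, metrics = r$metrics,
           summary = data.frame(
             metric = c("t_lysis_onset_s", "t_breakthrough_s"),
             value = c(r$metrics$t_start, r$metrics$t_breakthrough)))
    },
    pressure_sweep = {
      tab <- comparePressureDrops(
        cnd$pressure_drops_Pa, grid = scenarioGrid2D(config),
        kp = pr$kp, mp = pr$mp, fluid = pr$fluid, inlet = inlet,
        D = cnd$D_m2_s, t_end = num$t_end_s %||% 40000,
        metric_dt = num$metric_dt_s %||% 10,
        stop_btr = num$stop_btr %||% 1.55)
      list(history = tab,
           summary = data.frame(
             metric = paste0("t_breakthrough_", tab$dp, "Pa_s"),
             value = tab$t_breakthrough))
    })
  list(config = config, tier = config$tier, result = res,
       summary = res$summary, wall_time_s = proc.time()[[3]] - t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write legacy-ASCII VTK structured-points files for 2D fields
#'
#' @param fields named list of nx x ny matrices
#' @param grid [buildChannel()] grid
#' @param path output file
#' @return path, invisibly
#' @export
writeVTK <- function(fields, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "clotlysis field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               sprintf("ORIGIN %g %g 0", grid$dx / 2, grid$dy / 2),
               sprintf("SPACING %g %g 1", grid$dx, grid$dy),
               sprintf("POINT_DATA %d", grid$nx * grid$ny)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(fields[[nm]]), digits = 9, trim = TRUE,
                      scientific = TRUE), con)
  }
  invisible(path)
}

#' Write scenario outputs to disk
#'
#' Writes a JSON run manifest (config, metric summary, wall time, package
#' version, config hash) plus, depending on the tier and requested formats,
#' CSV time series and VTK snapshots of the 2D lysed-fraction fields. File
#' naming is deterministic; a rerun with the same config overwrites
#' byte-identically (the manifest's wall-time field excepted).
#'
#' @param run result of [runScenario()]
#' @param dir output directory (created if needed)
#' @return character vector of files written
#' @export
writeOutputs <- function(run, dir = run$config$output$dir %||% "clotlysis-out") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, run$config$name)
  files <- character(0)
  formats <- run$config$output$formats %||% c("csv", "json")
  h <- run$result$history
  empty <- is.null(h) ||
    (is.data.frame(h) && nrow(h) == 0) ||
    (inherits(h, "lysis_history") && length(h$time) == 0)
  if (empty) warning("empty history: writing manifest only")

  if ("csv" %in% formats && !empty) {
    if (is.data.frame(h)) {
      f <- paste0(stem, "-history.csv")
      utils::write.csv(h, f, row.names = FALSE)
      files <- c(files, f)
    } else if (inherits(h, "sim1d_history")) {
      f <- paste0(stem, "-front.csv")
      utils::write.csv(h$front, f, row.names = FALSE)
      files <- c(files, f)
      for (nm in names(h$snapshots)) {
        f <- paste0(stem, "-profile-", nm, ".csv")
        utils::write.csv(h$snapshots[[nm]], f, row.names = FALSE)
        files <- c(files, f)
      }
    } else if (inherits(h, "lysis_history")) {
      f <- paste0(stem, "-btr.csv")
      utils::write.csv(breakthroughRatio(h), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if ("vtk" %in% formats && inherits(h, "lysis_history")) {
    for (nm in names(h$snapshots)) {
      s <- h$snapshots[[nm]]
      f <- paste0(stem, "-", sub("snap", "btr", nm), ".vtk")
      writeVTK(list(fraction_lysed = s$frac), h$grid, f)
      files <- c(files, f)
    }
  }
  manifest <- list(
    name = run$config$name, tier = run$tier,
    package_version = as.character(utils::packageVersion("clotlysis")),
    config = run$config,
    config_hash = configHash(run$config),
    wall_time_s = run$wall_time_s,
    metrics = if (!is.null(run$summary))
      stats::setNames(as.list(run$summary$value), run$summary$metric),
    files = basename(files))
  f <- paste0(stem, "-manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(files, f)
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' Subcommands: `run <config.yaml|scenario-name> [--out DIR]`,
#' `list-scenarios`, `validate <config.yaml>`. A `--seed` option is accepted
#' for interface stability and recorded in the manifest; the model is fully
#' deterministic. Returns (rather than calls) the exit code: 0 success,
#' 1 runtime failure, 2 configuration error.
#'
#' @param argv character vector of arguments (e.g. `commandArgs(TRUE)`)
#' @return integer exit code
#' @export
runCli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: clotlysis <command> [...]",
    "  run <config.yaml | scenario-name> [--out DIR] [--seed N] [--verbose]",
    "  list-scenarios",
    "  validate <config.yaml>", sep = "\n")
  if (length(argv) == 0) { message(usage); return(2L) }
  cmd <- argv[1]; rest <- argv[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) == 0) return(default)
    rest[i[1] + 1]
  }
  if (cmd == "list-scenarios") {
    for (nm in names(referenceScenarios())) cat(nm, "\n")
    return(0L)
  }
  if (cmd == "validate") {
    if (length(rest) < 1) { message(usage); return(2L) }
    ok <- tryCatch({ loadScenario(rest[1]); TRUE },
                   error = function(e) { message(conditionMessage(e)); FALSE })
    return(if (ok) 0L else 2L)
  }
  if (cmd == "run") {
    if (length(rest) < 1) { message(usage); return(2L) }
    target <- rest[1]
    config <- tryCatch({
      if (file.exists(target)) loadScenario(target)
      else {
        sc <- referenceScenarios()
        if (!target %in% names(sc))
          stop("no such file or scenario: ", target, call. = FALSE)
        sc[[target]]
      }
    }, error = function(e) { message(conditionMessage(e)); NULL })
    if (is.null(config)) return(2L)
    seed <- opt("--seed")
    out <- tryCatch({
      run <- runScenario(config, verbose = "--verbose" %in% rest)
      if (!is.null(seed)) run$config$output$seed_recorded <- as.integer(seed)
      files <- writeOutputs(run, opt("--out", config$output$dir %||%
                                       "clotlysis-out"))
      message("wrote: ", paste(files, collapse = ", "))
      0L
    }, error = function(e) { message(conditionMessage(e)); 1L })
    return(out)
  }
  message(usage)
  2L
}
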