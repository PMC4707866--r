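#' Fibrin microstructure parameters
#'
#' Bundles the constants of the fibrin microstructure model: the clot-average
#' fibrin density, the initial fibre radius, the fibrin monomer molar mass
#' (340 kDa), the fibre-internal fibrin concentration that sets the initial
#' solid fraction, per-species binding-site capacities, and the permeability
#' regularisation. Derived quantities `n0_uM` (initial fibrin concentration in
#' uM) and `eps0` (initial voidage) are computed on construction.
#'
#' Units at this boundary: densities in mg/ml, radii in nm, molar mass in
#' g/mol. Internally concentrations are uM and lengths SI.
#'
#' @param fibrin_density_mg_ml clot-average fibrin density (mg/ml). Default
#'   0.28 mg/ml, a typical plasma-clot value.
#' @param fibre_radius_nm initial fibrin fibre radius R_f0 (nm). Default 250.
#' @param monomer_mass_g_mol fibrin monomer molar mass (g/mol). Default 340000;
#'   note 2 mg/ml of fibrin is then 5.88 uM.
#' @param fibre_fibrin_mg_ml fibrin mass per unit fibre volume (mg/ml). Sets the
#'   fibre solid fraction phi0 = fibrin_density/fibre_fibrin and hence the
#'   initial voidage eps0 = 1 - phi0. Default 11.2 mg/ml gives eps0 = 0.975 and
#'   an initial Davies permeability ~1e-12 m2, in the measured range for
#'   fibrin gels of comparable density.
#' @param binding_sites_per_monomer named numeric, binding sites per fibrin
#'   monomer for the two site classes: `tPA` (its own class) and `PLG` (shared
#'   by plasminogen and plasmin). The PLG value is calibrated so a 2 uM plasma
#'   pool equilibrates to 34.9 uM bound plasminogen.
#' @param k_max_m2 permeability cap (m2) standing in for the infinite
#'   permeability of fully lysed clot.
#' @param voidage_lysed_threshold voidage at or above which a cell is treated
#'   as fully lysed open fluid (Darcy resistance dropped entirely).
#' @param theta_exponent exponent q in theta_alpha = theta_alpha0*(R_f/R_f0)^q.
#'   2 (default) scales sites with remaining fibrin mass; 1 scales with fibre
#'   surface area.
#' @param permeability_fn function(eps, R_f_m, p) -> m2; defaults to
#'   [daviesPermeability()].
#' @return object of class `micro_params`
#' @export
microParams <- function(fibrin_density_mg_ml = 0.28,
                        fibre_radius_nm = 250,
                        monomer_mass_g_mol = 340000,
                        fibre_fibrin_mg_ml = 11.2,
                        binding_sites_per_monomer = c(tPA = 5, PLG = 98.8833),
                        k_max_m2 = 1e-6,
                        voidage_lysed_threshold = 0.9999,
                        theta_exponent = 2,
                        permeability_fn = daviesPermeability) {
  if (fibrin_density_mg_ml <= 0)
    stop("fibrin_density_mg_ml must be > 0", call. = FALSE)
  if (fibre_radius_nm <= 0)
    stop("fibre_radius_nm must be > 0", call. = FALSE)
  if (monomer_mass_g_mol <= 0)
    stop("monomer_mass_g_mol must be > 0", call. = FALSE)
  if (fibre_fibrin_mg_ml <= fibrin_density_mg_ml)
    stop("fibre_fibrin_mg_ml must exceed fibrin_density_mg_ml (solid fraction < 1)",
         call. = FALSE)
  if (!all(c("tPA", "PLG") %in% names(binding_sites_per_monomer)))
    stop("binding_sites_per_monomer needs entries 'tPA' and 'PLG'", call. = FALSE)
  if (voidage_lysed_threshold <= 0 || voidage_lysed_threshold >= 1)
    stop("voidage_lysed_threshold must lie in (0, 1)", call. = FALSE)
  if (!theta_exponent %in% c(1, 2))
    stop("theta_exponent must be 1 or 2", call. = FALSE)

  # mg/ml / (g/mol) = mmol/ml = mol/l; -> uM
  n0_uM <- fibrin_density_mg_ml / monomer_mass_g_mol * 1e6
  phi0 <- fibrin_density_mg_ml / fibre_fibrin_mg_ml
  eps0 <- 1 - phi0
  if (eps0 <= 0 || eps0 >= 1)
    stop("derived initial voidage must lie in (0, 1)", call. = FALSE)

  p <- list(
    fibrin_density_mg_ml = fibrin_density_mg_ml,
    fibre_radius_nm = fibre_radius_nm,
    monomer_mass_g_mol = monomer_mass_g_mol,
    fibre_fibrin_mg_ml = fibre_fibrin_mg_ml,
    binding_sites_per_monomer = binding_sites_per_monomer,
    k_max_m2 = k_max_m2,
    voidage_lysed_threshold = voidage_lysed_threshold,
    theta_exponent = theta_exponent,
    permeability_fn = permeability_fn,
    n0_uM = n0_uM,
    eps0 = eps0,
    theta0_uM = binding_sites_per_monomer * n0_uM
  )
  class(p) <- "micro_params"
  p
}

#' @export
print.micro_params <- function(x, ...) {
  cat("<micro_params>\n")
  cat(sprintf("  fibrin density : %.3g mg/ml (n0 = %.4g uM)\n",
              x$fibrin_density_mg_ml, x$n0_uM))
  cat(sprintf("  fibre radius   : %.3g nm\n", x$fibre_radius_nm))
  cat(sprintf("  initial voidage: %.4f\n", x$eps0))
  cat(sprintf("  theta0 (uM)    : tPA %.3g, PLG class %.3g\n",
              x$theta0_uM[["tPA"]], x$theta0_uM[["PLG"]]))
  invisible(x)
}

#' Fibrinolysis kinetic parameters
#'
#' Rate-constant registry for the fibrinolysis reaction system: reversible
#' surface adsorption for tPA, plasminogen (PLG) and plasmin (PLS),
#' Michaelis-Menten plasmin generation on the fibrin surface, fibrin lysis by
#' bound plasmin, solubilization of bound species as the supporting fibrin is
#' dissolved, and second-order inhibition of free plasmin by antiplasmin (AP,
#' well-mixed tier only).
#'
#' The defaults are a literature-sourced set (Diamond-Anand lineage
#' dissociation constants; fibrin-stimulated Michaelis-Menten constants) with
#' two calibrated values: the shared PLG/PLS binding-site capacity lives in
#' [microParams()], and `k_cat` is calibrated so that the reference well-mixed
#' scenario (plasminogen-equilibrated clot + 50 nM tPA) completes lysis at
#' about 90 s.
#'
#' @param k_ads named adsorption rate constants (1/uM/s) for tPA, PLG, PLS
#' @param k_rev named desorption rate constants (1/s)
#' @param k2 Michaelis-Menten turnover for plasmin generation (1/s)
#' @param K_M Michaelis constant for bound plasminogen (uM)
#' @param k_cat fibrin cleavage rate of bound plasmin (1/s)
#' @param gamma solubilization rate: plasmin cuts needed to cleave one unit of
#'   fibrin (dimensionless); lysis advances at (k_cat/gamma)*S_PLS
#' @param kappa solubilization constant; release flux is
#'   kappa*S_alpha*(dL/dt)/(n0-L), which drives all bound phases to exactly
#'   zero at complete lysis when kappa = 1
#' @param k_AP free-phase plasmin inhibition rate by antiplasmin (1/uM/s)
#' @param k_loss optional first-order plasmin activity loss (1/s); 0 unless
#'   emulating assay conditions where plasmin loses activity over time
#' @param plasma_volume_ratio plasma-pool-to-clot volume ratio V_r of the
#'   well-mixed tier. The free phase is a stirred pool of V_r clot volumes of
#'   plasma plus the clot's own pore fluid; V_r = 0 recovers a closed
#'   clot-only system. Default 98.74, pinned by the equilibrium partition of a
#'   2 uM plasminogen pool (free 1.65 uM vs 34.9 uM bound per clot volume).
#' @return object of class `kinetic_params`
#' @export
kineticParams <- function(k_ads = c(tPA = 0.1, PLG = 0.1, PLS = 0.1),
                          k_rev = c(tPA = 0.058, PLG = 0.22, PLS = 0.057),
                          k2 = 1.5,
                          K_M = 0.16,
                          k_cat = 1.3,
                          gamma = 160,
                          kappa = 1,
                          k_AP = 10,
                          k_loss = 0,
                          plasma_volume_ratio = 98.7393) {
  sp <- c("tPA", "PLG", "PLS")
  if (!all(sp %in% names(k_ads)) || !all(sp %in% names(k_rev)))
    stop("k_ads and k_rev need named entries for tPA, PLG, PLS", call. = FALSE)
  k_ads <- k_ads[sp]; k_rev <- k_rev[sp]
  if (any(c(k_ads, k_rev, k2, k_cat, kappa, k_AP, k_loss) < 0))
    stop("rate constants must be >= 0", call. = FALSE)
  if (K_M <= 0) stop("K_M must be > 0", call. = FALSE)
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (plasma_volume_ratio < 0)
    stop("plasma_volume_ratio must be >= 0", call. = FALSE)
  p <- list(k_ads = k_ads, k_rev = k_rev, k2 = k2, K_M = K_M,
            k_cat = k_cat, gamma = gamma, kappa = kappa, k_AP = k_AP,
            k_loss = k_loss, plasma_volume_ratio = plasma_volume_ratio)
  class(p) <- "kinetic_params"
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  k_ads (1/uM/s): tPA %.3g  PLG %.3g  PLS %.3g\n",
              x$k_ads[["tPA"]], x$k_ads[["PLG"]], x$k_ads[["PLS"]]))
  cat(sprintf("  k_rev (1/s)   : tPA %.3g  PLG %.3g  PLS %.3g\n",
              x$k_rev[["tPA"]], x$k_rev[["PLG"]], x$k_rev[["PLS"]]))
  cat(sprintf("  MM: k2 %.3g 1/s, K_M %.3g uM; lysis: k_cat %.3g 1/s, gamma %.3g\n",
              x$k2, x$K_M, x$k_cat, x$gamma))
  cat(sprintf("  kappa %.3g, k_AP %.3g 1/uM/s, V_r %.4g\n",
              x$kappa, x$k_AP, x$plasma_volume_ratio))
  invisible(x)
}

#' Blood properties
#'
#' Newtonian fluid properties of blood used by the flow tier.
#'
#' @param density_kg_m3 blood density (kg/m3)
#' @param viscosity_Pa_s dynamic viscosity (Pa s)
#' @return object of class `fluid_props`
#' @export
fluidProps <- function(density_kg_m3 = 1050, viscosity_Pa_s = 3.5e-3) {
  if (density_kg_m3 <= 0 || viscosity_Pa_s <= 0)
    stop("fluid density and viscosity must be > 0", call. = FALSE)
  structure(list(density = density_kg_m3, viscosity = viscosity_Pa_s),
            class = "fluid_props")
}
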