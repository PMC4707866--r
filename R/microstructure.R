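# Fibrin microstructure model: lysis is a homogeneous shrinkage of the fibre
# radius, which drives voidage, binding-site density and permeability.

#' Fibre radius as a function of lysed fibrin
#'
#' Fibrin mass per unit fibre length scales with the cross-section R_f^2, so
#' homogeneous radial shrinkage gives R_f = R_f0 * sqrt((n0 - L)/n0).
#'
#' @param L lysed fibrin (uM), in `[0, n0]`; vectorised
#' @param p [microParams()]
#' @return fibre radius in nm
#' @export
fibreRadius <- function(L, p) {
  n0 <- p$n0_uM
  if (any(L < -1e-12 * n0) || any(L > n0 * (1 + 1e-12)))
    stop("L must lie in [0, n0]", call. = FALSE)
  L <- pmin(pmax(L, 0), n0)
  p$fibre_radius_nm * sqrt((n0 - L) / n0)
}

#' Clot voidage as a function of fibre radius
#'
#' The solid fraction scales with fibre cross-section:
#' eps = 1 - (1 - eps0) * (R_f/R_f0)^2, so eps runs from the initial voidage
#' eps0 (intact clot) to 1 (fully lysed, all fluid).
#'
#' @param R_f fibre radius (nm), in `[0, R_f0]`; vectorised
#' @param p [microParams()]
#' @return voidage (dimensionless)
#' @export
clotVoidage <- function(R_f, p) {
  R0 <- p$fibre_radius_nm
  if (any(R_f < -1e-12 * R0) || any(R_f > R0 * (1 + 1e-12)))
    stop("R_f must lie in [0, R_f0]", call. = FALSE)
  R_f <- pmin(pmax(R_f, 0), R0)
  1 - (1 - p$eps0) * (R_f / R0)^2
}

#' Binding-site density as a function of fibre radius
#'
#' theta_alpha(R_f) = theta_alpha0 * (R_f/R_f0)^q with q = 2 by default
#' (sites proportional to remaining fibrin mass; q = 1 scales with fibre
#' surface area instead, selectable via `theta_exponent` in [microParams()]).
#' Plasmin occupies the plasminogen site class, so `species = "PLS"` returns
#' the shared PLG-class capacity.
#'
#' @param R_f fibre radius (nm); vectorised
#' @param species one of "tPA", "PLG", "PLS"
#' @param p [microParams()]
#' @return binding-site concentration (uM)
#' @export
bindingSiteDensity <- function(R_f, species, p) {
  cls <- siteClass(species)
  R0 <- p$fibre_radius_nm
  if (any(R_f < -1e-12 * R0) || any(R_f > R0 * (1 + 1e-12)))
    stop("R_f must lie in [0, R_f0]", call. = FALSE)
  R_f <- pmin(pmax(R_f, 0), R0)
  p$theta0_uM[[cls]] * (R_f / R0)^p$theta_exponent
}

# site-class lookup; plasmin binds the plasminogen class
siteClass <- function(species) {
  valid <- c(tPA = "tPA", PLG = "PLG", PLS = "PLG")
  if (!species %in% names(valid))
    stop("unknown species '", species, "'; valid: tPA, PLG, PLS", call. = FALSE)
  valid[[species]]
}

#' Davies permeability of a fibrous bed
#'
#' k = R_f^2 / (16 phi^1.5 (1 + 56 phi^3)) with solid fraction phi = 1 - eps,
#' the Davies correlation for flow through fibrous media. The result is capped
#' at `k_max_m2`, which regularises the divergence of the permeability as the
#' clot is completely lysed; phi <= 0 returns the cap.
#'
#' @param eps voidage; vectorised
#' @param R_f fibre radius (nm, same length or scalar)
#' @param p [microParams()]
#' @return permeability (m2)
#' @export
daviesPermeability <- function(eps, R_f, p) {
  if (any(eps < p$eps0 - 1e-9) || any(eps > 1 + 1e-12))
    stop("eps must lie in [eps0, 1]", call. = FALSE)
  phi <- 1 - eps
  R_m <- R_f * 1e-9
  k <- ifelse(phi <= 0, p$k_max_m2,
              R_m^2 / (16 * phi^1.5 * (1 + 56 * phi^3)))
  pmin(k, p$k_max_m2)
}

#' Clot permeability
#'
#' Dispatches to the pluggable permeability correlation in [microParams()]
#' (Davies by default).
#'
#' @inheritParams daviesPermeability
#' @return permeability (m2)
#' @export
clotPermeability <- function(eps, R_f, p) p$permeability_fn(eps, R_f, p)

#' Clot state at a given lysed amount
#'
#' Evaluates the whole microstructure chain L -> R_f -> (eps, theta, k).
#'
#' @param L lysed fibrin (uM); vectorised
#' @param p [microParams()]
#' @return list of class `clot_state`: `L`, `R_f` (nm), `voidage`,
#'   `theta` (uM, per site class), `permeability` (m2)
#' @export
clotStateFromL <- function(L, p) {
  R_f <- fibreRadius(L, p)
  eps <- clotVoidage(R_f, p)
  st <- list(
    L = L,
    R_f = R_f,
    voidage = eps,
    theta = list(tPA = bindingSiteDensity(R_f, "tPA", p),
                 PLG = bindingSiteDensity(R_f, "PLG", p)),
    permeability = clotPermeability(eps, R_f, p)
  )
  class(st) <- "clot_state"
  st
}

#' Initial (unlysed) clot state
#'
#' @param p [microParams()]
#' @return `clot_state` at L = 0: R_f = R_f0, eps = eps0, theta = theta0, k = k0
#' @export
initialClotState <- function(p) clotStateFromL(0, p)

#' @export
print.clot_state <- function(x, ...) {
  cat("<clot_state>\n")
  cat(sprintf("  L = %.4g uM, R_f = %.4g nm, voidage = %.4f, k = %.3g m2\n",
              x$L[1], x$R_f[1], x$voidage[1], x$permeability[1]))
  if (length(x$L) > 1) cat(sprintf("  (%d locations)\n", length(x$L)))
  invisible(x)
}
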