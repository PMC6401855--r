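# Solution chemistry: physical constants, species catalog, equilibrium
# constants and the bulk electrolyte reference state.

# number density of a 1 M solution, nm^-3
.M_TO_NM3 <- 0.60221408
# gas constant, kJ/(mol K)
.R_KJ <- 8.314462618e-3

#' Bjerrum length of the solvent
#'
#' @param eps_r relative dielectric constant of water (default 78.5).
#' @param T temperature in K.
#' @return Bjerrum length in nm (0.714 nm at defaults).
#' @export
bjerrum_length <- function(eps_r = 78.5, T = 298) {
  e <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23
  1e9 * e^2 / (4 * pi * eps0 * eps_r * kB * T)
}

#' Catalog of free species: valences and molecular volumes
#'
#' Species order is water, H+, OH-, Na+, Mg2+, Cl-. Volumes are the hydrated
#' molecular volumes used in the packing constraint; the ion volumes are
#' 0.18 nm3 for Mg2+ and 0.05 nm3 for Na+ and Cl-. The water volume (also
#' used for H+ and OH-) is the reference volume of the lattice, 0.030 nm3 by
#' default. `v_A`/`v_G` are the bare monomer volumes; a bound ion adds its own
#' volume to the complex (no reaction volume change).
#'
#' @param vw water (reference) volume, nm3.
#' @param vH,vOH volumes of H+ and OH-, default equal to `vw`.
#' @param vNa,vMg,vCl ion volumes, nm3.
#' @param v_A,v_G bare monomer volumes, nm3.
#' @param eps_r relative dielectric constant.
#' @return object of class `species_catalog`.
#' @export
species_catalog <- function(vw = 0.030, vH = vw, vOH = vw,
                            vNa = 0.05, vMg = 0.18, vCl = 0.05,
                            v_A = 0.30, v_G = 0.30, eps_r = 78.5) {
  v <- c(w = vw, H = vH, OH = vOH, Na = vNa, Mg = vMg, Cl = vCl)
  if (any(v <= 0) || v_A <= 0 || v_G <= 0)
    stop("all species volumes must be positive")
  structure(list(
    v = v,
    z = c(w = 0, H = 1, OH = -1, Na = 1, Mg = 2, Cl = -1),
    vw = vw, v_A = v_A, v_G = v_G, eps_r = eps_r
  ), class = "species_catalog")
}

#' Molar association constant from a standard binding free energy
#'
#' K0 = exp(-dG0 / (R T)); for the negative free energies of complex
#' formation this is the association constant referred to the molar standard
#' state (it is converted to the dimensionless reference-volume convention
#' by [assoc_constant_to_vw()]).
#'
#' @param dG0 standard free energy of the association reaction, kJ/mol.
#' @param T temperature, K.
#' @return dimensionless molar-standard-state association constant.
#' @export
equilibrium_constant_from_free_energy <- function(dG0, T = 298) {
  stopifnot(T > 0)
  exp(-dG0 / (.R_KJ * T))
}

#' Convert a molar association constant to the reference-volume convention
#'
#' Mass action in the model is written with dimensionless activities
#' rho(z) * vw, whose standard state is one molecule per reference volume
#' (1/vw = 55.5 M at vw = 0.030 nm3). A molar association constant K_M (units
#' 1/M) therefore maps to K0 = K_M / (0.6022 * vw).
#'
#' @param K_molar association constant in 1/M.
#' @param vw reference volume, nm3.
#' @return dimensionless association constant for rho*vw activities.
#' @export
assoc_constant_to_vw <- function(K_molar, vw) {
  stopifnot(vw > 0)
  K_molar / (.M_TO_NM3 * vw)
}

#' Protonation association constant from a pKa
#'
#' The molar acid constant is Ka = 10^(-pKa); the protonation (association)
#' constant is 1/Ka = 10^pKa in 1/M, converted to the reference-volume
#' convention.
#'
#' @param pKa acid dissociation pKa of the monomer.
#' @param vw reference volume, nm3.
#' @return dimensionless protonation constant for rho*vw activities.
#' @export
association_constant_from_pKa <- function(pKa, vw) {
  assoc_constant_to_vw(10^pKa, vw)
}

#' Binding constants for the six monomer equilibria
#'
#' Protonation (AH, GH), Na+ binding (ANa, GNa) and Mg2+ binding (AMg+, GMg+)
#' of adenine and guanine monomers. Mg2+ free energies are the experimentally
#' derived totals (-32.1 and -35.6 kJ/mol for A and G); pKa values are 3.5 (A)
#' and 1.6 (G). Na+ complexation is weak and no measured free energy exists
#' for these monomers; the default 0 kJ/mol corresponds to a 1 M^-1
#' association constant, typical of monovalent ion pairing, and is a model
#' choice (see the methods vignette). All reaction volume changes are zero:
#' a complex carries the volume of the monomer plus the bound ion.
#'
#' @param dG_AMg,dG_GMg Mg2+ binding free energies, kJ/mol.
#' @param dG_ANa,dG_GNa Na+ binding free energies, kJ/mol.
#' @param pKa_A,pKa_G monomer pKa values.
#' @param T temperature, K.
#' @param vw reference volume, nm3.
#' @param dv named reaction volume changes (nm3), default all zero.
#' @return object of class `binding_constants` with dimensionless constants
#'   `K` (names AH, GH, ANa, GNa, AMg, GMg) in the rho*vw convention.
#' @export
binding_constants <- function(dG_AMg = -32.1, dG_GMg = -35.6,
                              dG_ANa = 0, dG_GNa = 0,
                              pKa_A = 3.5, pKa_G = 1.6,
                              T = 298, vw = 0.030,
                              dv = c(AH = 0, GH = 0, ANa = 0, GNa = 0,
                                     AMg = 0, GMg = 0)) {
  K <- c(
    AH  = association_constant_from_pKa(pKa_A, vw),
    GH  = association_constant_from_pKa(pKa_G, vw),
    ANa = assoc_constant_to_vw(equilibrium_constant_from_free_energy(dG_ANa, T), vw),
    GNa = assoc_constant_to_vw(equilibrium_constant_from_free_energy(dG_GNa, T), vw),
    AMg = assoc_constant_to_vw(equilibrium_constant_from_free_energy(dG_AMg, T), vw),
    GMg = assoc_constant_to_vw(equilibrium_constant_from_free_energy(dG_GMg, T), vw)
  )
  if (any(K <= 0)) stop("equilibrium constants must be positive")
  dv_full <- c(AH = 0, GH = 0, ANa = 0, GNa = 0, AMg = 0, GMg = 0)
  dv_full[names(dv)] <- dv
  structure(list(
    K = K, dv = dv_full,
    dG = c(AMg = dG_AMg, GMg = dG_GMg, ANa = dG_ANa, GNa = dG_GNa),
    pKa = c(A = pKa_A, G = pKa_G), T = T, vw = vw
  ), class = "binding_constants")
}

#' Solve the bulk electrolyte reference state
#'
#' Fixes all bulk number densities from the salt concentrations and pH:
#' Na+ from NaCl, Mg2+ from MgCl2, H+ from the pH, OH- from the water ion
#' product, Cl- from electroneutrality and water from bulk incompressibility.
#' The exchange chemical potentials are chosen so the field expressions for
#' the free-species densities return exactly these values at pi = psi = 0
#' (the bulk gauge): all fields vanish in the far field.
#'
#' @param cNaCl,cMgCl2 bulk salt concentrations, mol/L.
#' @param pH bulk pH.
#' @param T temperature, K.
#' @param catalog a [species_catalog()].
#' @param pKw water ion product (14.0 at 298 K).
#' @return object of class `bulk_state` with number densities `rho` (nm^-3),
#'   dimensionless activities `a = rho * vw`, and exchange potentials `mu`.
#' @export
solve_bulk <- function(cNaCl, cMgCl2, pH, T = 298,
                       catalog = species_catalog(), pKw = 14) {
  stopifnot(cNaCl >= 0, cMgCl2 >= 0, pH > 0, pH < 14)
  rho <- c(
    w  = NA_real_,
    H  = 10^(-pH) * .M_TO_NM3,
    OH = 10^(-(pKw - pH)) * .M_TO_NM3,
    Na = cNaCl * .M_TO_NM3,
    Mg = cMgCl2 * .M_TO_NM3,
    Cl = NA_real_
  )
  rho["Cl"] <- rho["Na"] + 2 * rho["Mg"] + rho["H"] - rho["OH"]
  if (rho["Cl"] < 0)
    stop("implied bulk Cl- density is negative; unphysical input combination")
  occupied <- sum(rho[c("H", "OH", "Na", "Mg", "Cl")] *
                  catalog$v[c("H", "OH", "Na", "Mg", "Cl")])
  if (occupied >= 1)
    stop("ion volume fractions exceed one; no room for water in the bulk")
  rho["w"] <- (1 - occupied) / catalog$v["w"]
  a <- rho * catalog$vw
  structure(list(
    rho = rho, a = a, mu = log(a),
    pH = pH, pKw = pKw, T = T,
    cNaCl = cNaCl, cMgCl2 = cMgCl2,
    catalog = catalog, pressure = 0
  ), class = "bulk_state")
}
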