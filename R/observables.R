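# Observables computed from a converged solution: bound ions per chain,
# deprotonated polymer fraction, local pH, volume fractions, brush height
# and the per-state-point summary report.

# layers counted as "inside the brush"
.brush_layers <- function(sol, frac = 1e-4) {
  if (all(sol$phi_p <= 0)) return(integer(0))
  which(sol$phi_p > frac * max(sol$phi_p))
}

# per-chain count of monomers in one bound state, by exact monomer counting:
# dz * sum_k [rho_A f_As + rho_G f_Gs] / sigma_p
.per_chain <- function(sol, state) {
  dz <- sol$grid$dz
  dz * sum(sol$rho_A * sol$fractions$A[, state] +
           sol$rho_G * sol$fractions$G[, state]) / sol$sigma_p
}

#' Number of bound Mg2+ ions per chain
#'
#' Integrates the Mg-bound monomer density over the grid and divides by the
#' grafting density; bounded by the chain length.
#'
#' @param sol a converged `scft_solution`.
#' @return dimensionless count per chain.
#' @export
bound_mg_per_chain <- function(sol) {
  if (sol$sigma_p <= 0) stop("bound ions per chain undefined at zero grafting density")
  .per_chain(sol, "Mg")
}

#' Bound Na+ per chain
#' @inheritParams bound_mg_per_chain
#' @export
bound_na_per_chain <- function(sol) {
  if (sol$sigma_p <= 0) stop("bound ions per chain undefined at zero grafting density")
  .per_chain(sol, "Na")
}

#' Deprotonated (negatively charged) polymer fraction profile
#'
#' f_P-(z) = (f_A- phi_A + f_G- phi_G) / phi_p, the volume-share-weighted
#' fraction of bare (charged) monomers. Layers without polymer are `NA`.
#'
#' @param sol an `scft_solution`.
#' @return numeric vector over layers (NA where no polymer).
#' @export
deprotonated_fraction_profile <- function(sol) {
  num <- sol$fractions$A[, "minus"] * sol$rho_A +
         sol$fractions$G[, "minus"] * sol$rho_G
  den <- sol$rho_A + sol$rho_G
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

#' Local pH profile
#'
#' pH(z) = -log10 of the local molar H+ concentration; equals the bulk pH in
#' the far field.
#'
#' @param sol an `scft_solution`.
#' @return numeric vector over layers.
#' @export
local_ph_profile <- function(sol) {
  -log10(sol$rho[, "H"] / .M_TO_NM3)
}

#' Volume fraction profiles of all species
#'
#' @param sol an `scft_solution`.
#' @return matrix with columns polymer, w, H, OH, Na, Mg, Cl; rows sum to one
#'   within the solver tolerance.
#' @export
volume_fraction_profiles <- function(sol) {
  cbind(polymer = sol$phi_p, sol$phi_free)
}

#' First-moment brush height
#'
#' h = 2 * sum(z phi_p dz) / sum(phi_p dz), in nm.
#'
#' @param sol an `scft_solution`.
#' @return height in nm.
#' @export
brush_height <- function(sol) {
  if (all(sol$phi_p <= 0)) stop("brush height undefined with zero polymer")
  2 * sum(sol$grid$z * sol$phi_p) / sum(sol$phi_p)
}

#' Per-state-point summary report
#'
#' Gathers the scalar observables and their locations, the input echo and the
#' solver diagnostics into one list (serializable to JSON).
#'
#' @param sol an `scft_solution`.
#' @param brush_frac threshold (fraction of peak polymer volume fraction)
#'   defining the brush region, default 1e-4.
#' @return object of class `state_point_report`.
#' @export
state_point_report <- function(sol, brush_frac = 1e-4) {
  z <- sol$grid$z
  brush <- .brush_layers(sol, brush_frac)
  ph <- local_ph_profile(sol)
  fpm <- deprotonated_fraction_profile(sol)
  ph_b <- if (length(brush)) ph[brush] else ph
  peak <- which.max(sol$phi_p)
  structure(list(
    inputs = list(
      sequence = if (!is.null(sol$ensemble_meta$sequence)) sol$ensemble_meta$sequence else NA,
      sigma_p = sol$sigma_p,
      cNaCl_M = sol$bulk$cNaCl, cMgCl2_M = sol$bulk$cMgCl2,
      pH_bulk = sol$bulk$pH, T_K = sol$bulk$T
    ),
    N_Mg_per_chain = if (sol$sigma_p > 0) bound_mg_per_chain(sol) else 0,
    N_Na_per_chain = if (sol$sigma_p > 0) bound_na_per_chain(sol) else 0,
    brush_height_nm = if (any(sol$phi_p > 0)) brush_height(sol) else NA_real_,
    pH_min = min(ph_b), pH_min_z = z[which.min(replace(ph, -brush, Inf))],
    pH_max = max(ph_b), pH_max_z = z[which.max(replace(ph, -brush, -Inf))],
    phi_p_peak = sol$phi_p[peak], phi_p_peak_z = z[peak],
    f_Pminus_max = if (length(brush)) max(fpm[brush], na.rm = TRUE) else NA_real_,
    residual_norm = sol$residual_norm,
    iterations = sol$iterations,
    converged = sol$converged,
    ensemble = sol$ensemble_meta
  ), class = "state_point_report")
}

#' Polymer-weighted mean of a per-monomer state fraction over the brush
#'
#' Used for prose-level summaries such as "percent of monomers Mg-bound
#' inside the brush".
#'
#' @param sol an `scft_solution`.
#' @param state one of "minus", "H", "Na", "Mg".
#' @param brush_frac brush-region threshold.
#' @return dimensionless fraction in \[0, 1\].
#' @export
brush_mean_fraction <- function(sol, state = "Mg", brush_frac = 1e-4) {
  brush <- .brush_layers(sol, brush_frac)
  den <- sol$rho_A[brush] + sol$rho_G[brush]
  num <- sol$rho_A[brush] * sol$fractions$A[brush, state] +
         sol$rho_G[brush] * sol$fractions$G[brush, state]
  sum(num) / sum(den)
}
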