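# High-level state-point solving with continuation in grafting density.

#' Solve one thermodynamic state point
#'
#' Builds the bulk reservoir and the SCFT system and solves the field
#' equations. Cold starts ramp the grafting density geometrically from a
#' dilute value, warm-starting each rung from the previous converged fields
#' (dense brushes at high salt are strongly nonlinear); failed rungs are
#' bisected. A supplied `init` skips the ramp.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param sigma_p grafting density, chains/nm2.
#' @param cNaCl,cMgCl2 bulk salt concentrations, mol/L.
#' @param pH bulk pH.
#' @param T temperature, K.
#' @param constants a [binding_constants()].
#' @param catalog a [species_catalog()].
#' @param init optional starting fields (list with `pi`, `psi`).
#' @param control solver control list, see [solve_fields()].
#' @return an `scft_solution`.
#' @export
solve_state_point <- function(ensemble, sigma_p, cNaCl = 0.010, cMgCl2 = 0,
                              pH = 7, T = 298,
                              constants = binding_constants(T = T),
                              catalog = species_catalog(),
                              init = NULL, control = list()) {
  bulk <- solve_bulk(cNaCl, cMgCl2, pH, T, catalog)
  make_sys <- function(sp) scft_system(ensemble, sp, bulk, constants, catalog)
  if (!is.null(init) || sigma_p <= 0.005) {
    return(solve_fields(make_sys(sigma_p), init = init, control = control))
  }
  n_rungs <- ceiling(log(sigma_p / 0.005) / log(4))
  path <- sigma_p * 4^(-(n_rungs:0))
  sol <- NULL
  i <- 1
  guard <- 0
  while (i <= length(path)) {
    guard <- guard + 1
    if (guard > 4 * length(path) + 32)
      stop("continuation in grafting density failed to converge")
    sys_i <- make_sys(path[i])
    cand <- solve_fields(sys_i, init = if (is.null(sol)) NULL else sol$fields,
                         control = control)
    if (cand$converged) {
      sol <- cand
      i <- i + 1
    } else {
      prev <- if (i == 1) 0 else path[i - 1]
      mid <- if (prev > 0) sqrt(prev * path[i]) else path[i] / 4
      path <- append(path, mid, after = i - 1)
    }
  }
  sol
}
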