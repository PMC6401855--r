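# Independent small-scale references: analytic mass action at zero fields,
# brute-force extremization of the semi-grand potential on toy problems, and
# the canonical fixture grid.

#' Analytic monomer-state fractions in the non-interacting limit
#'
#' Direct evaluation of the four-state partition sum at pi = psi = 0 using
#' bulk activities; written independently of the solver path and used to
#' validate [monomer_state_fractions()].
#'
#' @param bulk a [solve_bulk()] state.
#' @param constants a [binding_constants()].
#' @return list of named fraction vectors `A` and `G`.
#' @export
noninteracting_fraction_oracle <- function(bulk, constants) {
  one <- function(KH, KNa, KMg) {
    terms <- c(minus = 1,
               H = KH * bulk$a[["H"]],
               Na = KNa * bulk$a[["Na"]],
               Mg = KMg * bulk$a[["Mg"]])
    terms / sum(terms)
  }
  list(A = one(constants$K[["AH"]], constants$K[["ANa"]], constants$K[["AMg"]]),
       G = one(constants$K[["GH"]], constants$K[["GNa"]], constants$K[["GMg"]]))
}

#' Construct a toy SCFT problem
#'
#' A few layers and a hand-written conformation list, small enough for direct
#' optimization over all field unknowns. Isolates the field solver from the
#' chain generator.
#'
#' @param nA,nG occupancy matrices (conformations x layers).
#' @param sigma_p grafting density, chains/nm2.
#' @param cNaCl,cMgCl2,pH,T bulk conditions.
#' @param dz layer width, nm.
#' @param n_layers grid size (default the occupancy width).
#' @param constants a [binding_constants()].
#' @param catalog a [species_catalog()].
#' @param polymer_charged `FALSE` for a neutral chain.
#' @return an [scft_system()].
#' @export
toy_problem <- function(nA, nG, sigma_p, cNaCl = 0.010, cMgCl2 = 0, pH = 7,
                        T = 298, dz = 0.3, n_layers = ncol(as.matrix(nA)),
                        constants = binding_constants(T = T),
                        catalog = species_catalog(),
                        polymer_charged = TRUE) {
  ens <- manual_ensemble(nA, nG, n_layers = n_layers, dz = dz)
  bulk <- solve_bulk(cNaCl, cMgCl2, pH, T, catalog)
  scft_system(ens, sigma_p, bulk, constants, catalog,
              polymer_charged = polymer_charged)
}

#' Brute-force field solution by direct extremization
#'
#' Maximizes the semi-grand potential per unit area over all 2 n_layers field
#' unknowns with BFGS and central-difference gradients — independent of the
#' Newton residual path. The solver must reproduce these fields on every toy
#' problem.
#'
#' @param sys a toy [scft_system()] (small dimensions).
#' @param reltol optimizer relative tolerance.
#' @return list with `fields` (`pi`, `psi`), the potential `W`, and the
#'   optimizer diagnostics.
#' @export
brute_force_field_solution <- function(sys, reltol = 1e-14) {
  L <- sys$L
  negW <- function(x) -grand_potential_per_area(
    sys, fields = list(pi = x[seq_len(L)], psi = x[L + seq_len(L)]))
  grad <- function(x) {
    g <- numeric(length(x))
    h <- 1e-6
    for (j in seq_along(x)) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      g[j] <- (negW(xp) - negW(xm)) / (2 * h)
    }
    g
  }
  fit <- stats::optim(rep(0, 2 * L), negW, grad, method = "BFGS",
                      control = list(maxit = 20000, reltol = reltol))
  # restart until stationary (each restart resets the BFGS metric)
  for (i in 1:6) {
    prev <- fit$par
    fit <- stats::optim(fit$par, negW, grad, method = "BFGS",
                        control = list(maxit = 20000, reltol = reltol))
    if (max(abs(fit$par - prev)) < 1e-9) break
  }
  # polish: diagonal-curvature Newton steps on the numeric gradient
  x <- fit$par
  h <- 1e-4
  for (i in 1:100) {
    g <- grad(x)
    if (max(abs(g)) < 1e-11) break
    f0 <- negW(x)
    for (j in seq_along(x)) {
      xp <- x; xm <- x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      cjj <- (negW(xp) - 2 * f0 + negW(xm)) / h^2
      if (is.finite(cjj) && cjj > 1e-12) x[j] <- x[j] - g[j] / cjj
    }
  }
  if (negW(x) <= fit$value + 1e-12) fit$par <- x
  fit$value <- negW(fit$par)
  list(fields = list(pi = fit$par[seq_len(L)], psi = fit$par[L + seq_len(L)]),
       W = -fit$value, convergence = fit$convergence,
       counts = fit$counts)
}

#' Canonical fixture state points
#'
#' The full study grid: three sequences x three grafting densities x four
#' MgCl2 concentrations at 10 mM NaCl, pH 7, 298 K, with the reduced
#' ensemble settings used by the test suite.
#'
#' @param ensemble_size reduced ensemble size for fast runs.
#' @param seed fixture seed.
#' @return data.frame with 36 rows.
#' @export
fixture_state_points <- function(ensemble_size = 3000, seed = 20181403) {
  grid <- expand.grid(
    sequence = c("A6G6", "G6A6", "(AG)6"),
    sigma_p = c(0.005, 0.05, 0.5),
    mgcl2_mM = c(0, 3, 50, 180),
    stringsAsFactors = FALSE
  )
  grid$nacl_mM <- 10
  grid$pH <- 7
  grid$T_K <- 298
  grid$ensemble_size <- ensemble_size
  grid$seed <- seed
  grid
}
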