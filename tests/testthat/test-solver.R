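test_that("the bare reservoir solves immediately to flat fields", {
  ens <- ci_ensemble()
  bulk <- solve_bulk(0.010, 0.003, 7)
  sol <- solve_fields(scft_system(ens, 0, bulk, binding_constants()))
  expect_true(sol$converged)
  expect_lte(sol$iterations, 2)
  expect_equal(max(abs(c(sol$fields$pi, sol$fields$psi))), 0)
  expect_equal(unname(sol$rho[50, ]), unname(bulk$rho), tolerance = 1e-14)
})

test_that("converged solutions satisfy every structural invariant", {
  sol <- ci_solution(0.05, 50)
  expect_true(sol$converged)
  L <- sol$grid$n_layers
  # packing in every layer
  expect_lt(max(abs(sol$residual[1:L])), 1e-8)
  phi <- volume_fraction_profiles(sol)
  expect_lt(max(abs(rowSums(phi) - 1)), 1e-8)
  # normalizations
  expect_lt(abs(sum(sol$P) - 1), 1e-12)
  expect_lt(max(abs(rowSums(sol$fractions$A) - 1)), 1e-13)
  expect_lt(max(abs(rowSums(sol$fractions$G) - 1)), 1e-13)
  # global electroneutrality (e/nm2)
  expect_lt(abs(sum(sol$rho_q) * sol$grid$dz), 1e-6)
  # bulk recovery in the top ten layers
  top <- (L - 9):L
  rel <- abs(sweep(sol$rho[top, ], 2, sol$bulk$rho, "/") - 1)
  expect_lt(max(rel), 1e-6)
  expect_lt(max(abs(sol$fields$pi[top])), 1e-7)
  # monomer-count conservation: dz * sum(rho_A + rho_G) = 12 sigma_p
  expect_equal(sol$grid$dz * sum(sol$rho_A + sol$rho_G), 12 * sol$sigma_p,
               tolerance = 1e-10)
  # no exponent clipping at convergence
  expect_false(sol$clipping_active)
})

test_that("mass action holds pointwise when re-evaluated from the profiles", {
  sol <- ci_solution(0.05, 3)
  K <- sol$constants$K
  aH <- sol$rho[, "H"] * 0.03
  aNa <- sol$rho[, "Na"] * 0.03
  aMg <- sol$rho[, "Mg"] * 0.03
  fA <- sol$fractions$A
  expect_equal(fA[, "H"] / fA[, "minus"], K[["AH"]] * aH, tolerance = 1e-10)
  expect_equal(fA[, "Na"] / fA[, "minus"], K[["ANa"]] * aNa, tolerance = 1e-10)
  expect_equal(fA[, "Mg"] / fA[, "minus"], K[["AMg"]] * aMg, tolerance = 1e-10)
  fG <- sol$fractions$G
  expect_equal(fG[, "H"] / fG[, "minus"], K[["GH"]] * aH, tolerance = 1e-10)
  expect_equal(fG[, "Mg"] / fG[, "minus"], K[["GMg"]] * aMg, tolerance = 1e-10)
})

test_that("solver fields match brute-force extremization of the potential", {
  sys <- toy_problem(toy_nA, toy_nG, sigma_p = 0.02, cNaCl = 0.010,
                     cMgCl2 = 0.001, n_layers = 3)
  sol <- solve_fields(sys)
  bf <- brute_force_field_solution(sys)
  expect_lt(max(abs(c(sol$fields$pi - bf$fields$pi,
                      sol$fields$psi - bf$fields$psi))), 1e-6)
  expect_lt(abs(grand_potential_per_area(sol) - bf$W), 1e-8)
  # no charged species: psi is identically zero
  sysn <- toy_problem(toy_nA, toy_nG, sigma_p = 0.02, cNaCl = 0, cMgCl2 = 0,
                      n_layers = 3, polymer_charged = FALSE)
  soln <- solve_fields(sysn)
  expect_equal(max(abs(soln$fields$psi)), 0)
  bfn <- brute_force_field_solution(sysn)
  expect_lt(max(abs(soln$fields$pi - bfn$fields$pi)), 1e-6)
})

test_that("the potential is stationary and maximal at the solution", {
  sys <- toy_problem(toy_nA, toy_nG, sigma_p = 0.02, cMgCl2 = 0.001,
                     n_layers = 3)
  sol <- solve_fields(sys)
  W0 <- grand_potential_per_area(sol)
  for (j in 1:3) for (eps in c(1e-3, -1e-3)) {
    f <- sol$fields
    f$pi[j] <- f$pi[j] + eps
    dW <- grand_potential_per_area(sys, fields = f) - W0
    expect_lt(dW, 0)
    expect_lt(abs(dW), 10 * eps^2)
  }
  # bare reservoir potential vanishes in the bulk gauge
  sys0 <- toy_problem(toy_nA, toy_nG, sigma_p = 0, cMgCl2 = 0.001,
                      n_layers = 3)
  expect_lt(abs(grand_potential_per_area(solve_fields(sys0))), 1e-14)
})

test_that("swapping the A/G labels and parameters leaves observables unchanged", {
  K <- binding_constants()
  Kswap <- binding_constants(dG_AMg = -35.6, dG_GMg = -32.1,
                             pKa_A = 1.6, pKa_G = 3.5)
  a <- solve_state_point(ci_ensemble("A6G6"), 0.05, cMgCl2 = 0.003,
                         constants = K)
  g <- solve_state_point(ci_ensemble("G6A6"), 0.05, cMgCl2 = 0.003,
                         constants = Kswap)
  expect_equal(a$phi_p, g$phi_p, tolerance = 1e-9)
  expect_equal(a$rho_q, g$rho_q, tolerance = 1e-9)
  expect_equal(a$rho_A, g$rho_G, tolerance = 1e-9)
  expect_equal(local_ph_profile(a), local_ph_profile(g), tolerance = 1e-9)
})

test_that("doubling the ensemble changes the polymer profile by under 2 percent", {
  # asserted at the default production ensemble size
  ens1 <- ci_ensemble(n = 1e5)
  ens2 <- ci_ensemble(n = 2e5)
  s1 <- solve_state_point(ens1, 0.05, cMgCl2 = 0.003)
  s2 <- solve_state_point(ens2, 0.05, cMgCl2 = 0.003)
  expect_lt(max(abs(s1$phi_p - s2$phi_p)), 0.02 * max(s1$phi_p))
})

test_that("grid refinement changes the toy potential at second order", {
  sysc <- toy_problem(toy_nA, toy_nG, sigma_p = 0.02, cMgCl2 = 0.001,
                      dz = 0.3, n_layers = 6)
  # same physical occupancies on a half-width grid (each layer split in two)
  split <- function(M) {
    out <- matrix(0, nrow(M), 2 * ncol(M))
    out[, seq(1, 2 * ncol(M), 2)] <- M
    out
  }
  sysf <- toy_problem(split(toy_nA), split(toy_nG), sigma_p = 0.02,
                      cMgCl2 = 0.001, dz = 0.15, n_layers = 12)
  sc <- solve_fields(sysc)
  sf <- solve_fields(sysf)
  # psi at the wall converges as O(dz^2): coarse and fine agree to a few %
  expect_equal(sc$fields$psi[1], sf$fields$psi[1], tolerance = 0.05)
})

test_that("non-convergence is reported, not hidden", {
  ens <- ci_ensemble()
  bulk <- solve_bulk(0.010, 0.180, 7)
  sys <- scft_system(ens, 0.5, bulk, binding_constants())
  sol <- solve_fields(sys, control = list(max_iter = 1))
  expect_false(sol$converged)
  expect_true(sol$residual_norm > 1e-8)
  expect_warning(grand_potential_per_area(sol), "non-converged")
})

test_that("continuation reaches the dense-brush corner states", {
  sol <- ci_solution(0.5, 180)
  expect_true(sol$converged)
  expect_lt(sol$residual_norm, 1e-8)
})
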