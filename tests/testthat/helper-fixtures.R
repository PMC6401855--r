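# Shared reduced-scale fixtures, generated once per test run.
# CI ensembles use 3000 accepted conformations at a fixed seed; profile-level
# conclusions at this size are validated by the ensemble-doubling test.

.fixture_env <- new.env(parent = emptyenv())

ci_ensemble <- function(spec = "A6G6", n = 3000, seed = 20181403) {
  key <- sprintf("%s_%d_%d", spec, n, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_ensemble(
      build_sequence(spec), chain_geometry(), scft_grid(),
      rotations_per_state = ceiling(n / (19683 * 0.25)) + 1,
      seed = seed, max_conformations = n)
  }
  .fixture_env[[key]]
}

ci_solution <- function(sigma_p, mgcl2_mM, spec = "A6G6", ...) {
  key <- sprintf("sol_%s_%g_%g", spec, sigma_p, mgcl2_mM)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- solve_state_point(
      ci_ensemble(spec), sigma_p, cNaCl = 0.010, cMgCl2 = mgcl2_mM / 1000,
      pH = 7, ...)
  }
  .fixture_env[[key]]
}

# hand-written two-conformation toy occupancies
toy_nA <- rbind(c(2, 0), c(1, 1))
toy_nG <- rbind(c(0, 1), c(1, 0))
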