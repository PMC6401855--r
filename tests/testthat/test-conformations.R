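test_that("torsion-state enumeration counts 3^(N-3) assignments", {
  expect_equal(nrow(enumerate_dihedral_states(1)), 1L)
  expect_equal(nrow(enumerate_dihedral_states(3)), 1L)
  expect_equal(ncol(enumerate_dihedral_states(3)), 0L)
  expect_equal(nrow(enumerate_dihedral_states(4)), 3L)
  expect_equal(nrow(enumerate_dihedral_states(12)), 19683L)
  expect_equal(ncol(enumerate_dihedral_states(12)), 9L)
})

test_that("all-trans embedding follows hand zig-zag geometry", {
  # rotation mapping the zig-zag axis onto +z: the axis bisects successive
  # bonds, each at (180 - bond_angle)/2 from it
  g <- chain_geometry(first_monomer_z = 0.15)
  al <- (180 - g$bond_angle) / 2 * pi / 180
  Rot <- matrix(c(cos(al), 0, sin(al), 0, 1, 0, -sin(al), 0, cos(al)), 3, 3)
  coords <- embed_conformation(rep(1L, 9), g, Rot)
  expect_false(is.null(coords))
  # per-bond rise along the axis is b sin(theta/2)
  rise <- g$bond_length * sin(g$bond_angle / 2 * pi / 180)
  expect_equal(coords[, 3], 0.15 + (0:11) * rise, tolerance = 1e-12)
})

test_that("straight-rod limit and wall rejection behave", {
  g <- chain_geometry(bond_angle = 180, first_monomer_z = 0.15)
  coords <- embed_conformation(rep(1L, 9), g)
  expect_equal(coords[, 3], 0.15 + (0:11) * 0.6, tolerance = 1e-12)
  # binned: every second layer 0,2,...,22 (0-based), one monomer each
  occ <- bin_to_layers(coords, build_sequence("A6G6"), scft_grid())
  expect_equal(which(occ$n_A + occ$n_G == 1), seq(1, 23, 2))
  expect_equal(sum(occ$n_A), 6L)
  expect_equal(sum(occ$n_G), 6L)
  # chain pointed at the wall is rejected
  flip <- diag(c(1, 1, -1)) %*% diag(c(1, -1, 1))  # proper rotation z -> -z
  expect_null(embed_conformation(rep(1L, 9), g, flip))
  # single monomer always accepted
  expect_equal(nrow(embed_conformation(integer(0), g, n_monomers = 1)), 1L)
})

test_that("binning uses half-open layers and conserves monomers", {
  grid <- scft_grid()
  seqA <- build_sequence("A1")
  co <- matrix(c(0, 0, 0.29), 1)
  expect_equal(which(bin_to_layers(co, seqA, grid)$n_A == 1), 1L)
  co[3] <- 0.30
  expect_equal(which(bin_to_layers(co, seqA, grid)$n_A == 1), 2L)
  expect_error(bin_to_layers(matrix(c(0, 0, 31), 1), seqA, grid), "beyond the grid")
})

test_that("compiled embedding matches the R reference", {
  g <- chain_geometry(first_monomer_z = 0.15)
  set.seed(42)
  for (rep_i in 1:5) {
    assign <- sample(1:3, 9, replace = TRUE)
    # random proper rotation via QR
    qr_ <- qr(matrix(rnorm(9), 3))
    Rot <- qr.Q(qr_)
    if (det(Rot) < 0) Rot[, 1] <- -Rot[, 1]
    cpp <- brushscft:::ris_embed_cpp(assign, 12L, g$bond_length, g$bond_angle,
                                     as.numeric(g$dihedral_states),
                                     g$first_monomer_z, Rot)
    loc <- brushscft:::.bond_directions(12, assign, g)
    ref <- rbind(0, apply(loc * g$bond_length, 2, cumsum)) %*% t(Rot)
    ref[, 3] <- ref[, 3] + 0.15
    expect_equal(cpp, ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("ensemble generation conserves monomers, respects the wall and the seed", {
  ens <- ci_ensemble()
  expect_equal(ens$n_conformations, 3000)
  expect_true(all(rowSums(ens$nA) == 6))
  expect_true(all(rowSums(ens$nG) == 6))
  expect_true(all(ens$nA >= 0) && all(ens$nG >= 0))
  expect_true(sum(ens$m) == ens$n_conformations)
  expect_true(ens$acceptance_rate <= 1)
  # determinism: regenerating with the same seed is identical
  ens2 <- generate_ensemble(build_sequence("A6G6"), chain_geometry(),
                            scft_grid(), rotations_per_state = 1,
                            seed = 20181403, max_conformations = 3000)
  expect_identical(ens$nA, ens2$nA)
  expect_identical(ens$nG, ens2$nG)
  expect_identical(ens$m, ens2$m)
  # a different seed is not
  ens3 <- generate_ensemble(build_sequence("A6G6"), chain_geometry(),
                            scft_grid(), rotations_per_state = 1,
                            seed = 7, max_conformations = 3000)
  expect_false(identical(ens$nA, ens3$nA))
})

test_that("label swap: G6A6 ensemble is the A6G6 ensemble with A/G exchanged", {
  a <- ci_ensemble("A6G6")
  g <- ci_ensemble("G6A6")
  expect_identical(a$nA, g$nG)
  expect_identical(a$nG, g$nA)
  expect_identical(a$m, g$m)
})

test_that("N = 1 chains give a single occupancy class for any rotation count", {
  ens <- generate_ensemble(build_sequence("A1"), chain_geometry(),
                           scft_grid(), rotations_per_state = 7, seed = 3)
  expect_equal(nrow(ens$nA), 1L)
  expect_equal(ens$n_conformations, 7)
})

test_that("ensemble cache round-trips bit-exactly", {
  ens <- ci_ensemble()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_identical(matrix(as.integer(ens$nA), nrow(ens$nA)), back$nA)
  expect_identical(matrix(as.integer(ens$nG), nrow(ens$nG)), back$nG)
  expect_identical(ens$m, back$m)
  expect_identical(back$geometry$bond_length, ens$geometry$bond_length)
  expect_identical(back$n_conformations, ens$n_conformations)
  expect_identical(back$seq$monomers, ens$seq$monomers)
})
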