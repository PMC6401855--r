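# RIS conformational ensemble of a grafted chain: enumeration, embedding,
# layer binning and ensemble generation. A pure-R embedding serves as the
# reference implementation; bulk generation runs through compiled code.

#' Enumerate all torsion-state assignments of a linear bead chain
#'
#' A chain of N beads has N - 1 bonds, N - 2 bond angles and N - 3 torsions;
#' each torsion takes one of the three rotational isomeric states.
#'
#' @param n_monomers number of beads, >= 1.
#' @return integer matrix with 3^max(N-3, 0) rows, one column per torsion
#'   (values 1..3 indexing the geometry's `dihedral_states`). A chain with no
#'   torsions yields a single empty assignment (one row, zero columns).
#' @export
enumerate_dihedral_states <- function(n_monomers) {
  stopifnot(n_monomers >= 1)
  d <- max(n_monomers - 3, 0)
  if (d == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  as.matrix(rev(expand.grid(rep(list(1:3), d), KEEP.OUT.ATTRS = FALSE)))[, d:1, drop = FALSE]
}

# Unit bond directions for one torsion assignment, chain in its local frame.
# Internal bond-angle convention: successive bond vectors meet at the
# supplement (180 - bond_angle); trans (180 deg) continues the planar zig-zag.
.bond_directions <- function(n_monomers, assignment, geometry) {
  nb <- n_monomers - 1
  u <- matrix(0, nrow = max(nb, 0), ncol = 3)
  if (nb == 0) return(u)
  ths <- (180 - geometry$bond_angle) * pi / 180  # angle between bond vectors
  u[1, ] <- c(0, 0, 1)
  if (nb >= 2) u[2, ] <- c(sin(ths), 0, cos(ths))
  if (nb >= 3) {
    phis <- geometry$dihedral_states[assignment] * pi / 180
    for (i in 3:nb) {
      e1 <- u[i - 1, ]
      p <- u[i - 2, ] - sum(u[i - 2, ] * e1) * e1
      np <- sqrt(sum(p^2))
      if (np < 1e-12) {            # collinear previous bonds: no torsion defined
        u[i, ] <- cos(ths) * e1
        if (abs(sin(ths)) > 1e-12) u[i, ] <- u[i, ] + sin(ths) * c(1, 0, 0)
        next
      }
      ep <- p / np
      en <- c(e1[2] * ep[3] - e1[3] * ep[2],
              e1[3] * ep[1] - e1[1] * ep[3],
              e1[1] * ep[2] - e1[2] * ep[1])
      phi <- phis[i - 2]
      u[i, ] <- cos(ths) * e1 - sin(ths) * (cos(phi) * ep + sin(phi) * en)
    }
  }
  u
}

#' Embed one conformation above the grafting surface
#'
#' Builds the chain from its torsion assignment in a local frame, applies a
#' rigid-body rotation about the grafted monomer, and places monomer 1 at
#' (0, 0, first_monomer_z). Any monomer centre below the surface rejects the
#' conformation (a normal outcome, returned as `NULL`).
#'
#' @param assignment integer vector of torsion-state indices (length N - 3),
#'   or an integer N for the all-trans chain of N monomers.
#' @param geometry a [chain_geometry()]; `first_monomer_z` must be set.
#' @param rotation 3x3 proper rotation matrix (default identity).
#' @param n_monomers number of beads; inferred as `length(assignment) + 3`
#'   when omitted.
#' @return N x 3 matrix of coordinates (nm), or `NULL` if rejected.
#' @export
embed_conformation <- function(assignment, geometry, rotation = diag(3),
                               n_monomers = NULL) {
  if (is.null(n_monomers)) n_monomers <- length(assignment) + 3L
  stopifnot(n_monomers >= 1)
  z0 <- geometry$first_monomer_z
  if (is.null(z0)) stop("geometry$first_monomer_z must be set for embedding")
  u <- .bond_directions(n_monomers, assignment, geometry)
  coords <- matrix(0, nrow = n_monomers, ncol = 3)
  if (n_monomers > 1)
    coords[-1, ] <- apply(u * geometry$bond_length, 2, cumsum)
  coords <- coords %*% t(rotation)
  coords[, 3] <- coords[, 3] + z0
  if (any(coords[, 3] < 0)) return(NULL)
  coords
}

#' Bin monomer coordinates into grid layers
#'
#' Layers are half-open intervals \[k dz, (k+1) dz); a monomer at z belongs to
#' layer floor(z / dz) + 1 (1-based).
#'
#' @param coords N x 3 coordinate matrix with all z >= 0.
#' @param seq a [build_sequence()] chain of matching length.
#' @param grid a [scft_grid()].
#' @return list with integer vectors `n_A` and `n_G` of per-layer occupancies.
#' @export
bin_to_layers <- function(coords, seq, grid) {
  z <- coords[, 3]
  stopifnot(all(z >= 0), nrow(coords) == seq$n)
  k <- floor(z / grid$dz) + 1L
  if (any(k > grid$n_layers))
    stop("monomer coordinate beyond the grid extent")
  isA <- seq$monomers == "A"
  list(
    n_A = tabulate(k[isA], nbins = grid$n_layers),
    n_G = tabulate(k[!isA], nbins = grid$n_layers)
  )
}

#' Generate the RIS conformational ensemble of a grafted chain
#'
#' Enumerates all torsion assignments, pre-builds each chain in its local
#' frame, and sweeps uniform random rigid-body rotations (uniform over SO(3)
#' via random unit quaternions) across the full assignment set; conformations
#' with any monomer below the surface, or beyond the grid, are rejected.
#' Accepted conformations are binned into layers and identical occupancy
#' vectors are collapsed with multiplicities. Deterministic given the seed.
#'
#' @param seq a [build_sequence()] chain.
#' @param geometry a [chain_geometry()]; a `NULL` `first_monomer_z` is set to
#'   half a layer width.
#' @param grid a [scft_grid()].
#' @param rotations_per_state rotations swept per torsion assignment.
#' @param seed RNG seed (own generator; independent of R's RNG state).
#' @param max_conformations stop after this many accepted conformations.
#' @return object of class `conformation_ensemble`: occupancy matrices `nA`,
#'   `nG` (unique conformations x occupied layers), multiplicities `m`,
#'   accepted count `n_conformations`, `acceptance_rate`, `layers_used`, and
#'   the generation record (geometry, grid, seed).
#' @export
generate_ensemble <- function(seq, geometry = chain_geometry(),
                              grid = scft_grid(), rotations_per_state = 20,
                              seed = 1, max_conformations = Inf) {
  stopifnot(rotations_per_state >= 1)
  if (is.null(geometry$first_monomer_z))
    geometry$first_monomer_z <- grid$dz / 2
  isA <- seq$monomers == "A"
  res <- ris_ensemble_cpp(
    isA, geometry$bond_length, geometry$bond_angle,
    as.numeric(geometry$dihedral_states), geometry$first_monomer_z,
    grid$n_layers, grid$dz, as.integer(rotations_per_state),
    as.numeric(seed),
    if (is.finite(max_conformations)) as.numeric(max_conformations) else -1
  )
  if (res$accepted == 0)
    stop("empty ensemble: every embedding was rejected; geometry and grid are inconsistent")
  Lc <- res$layers_used
  structure(list(
    nA = res$nA, nG = res$nG, m = as.numeric(res$m),
    n_conformations = as.integer(res$accepted),
    acceptance_rate = res$accepted / res$attempted,
    layers_used = Lc,
    n_layers = grid$n_layers, dz = grid$dz,
    seq = seq, geometry = geometry,
    rotations_per_state = rotations_per_state, seed = seed
  ), class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf(
    "conformation_ensemble: %s, %d accepted (%d unique occupancies), %.1f%% acceptance, %d layers occupied\n",
    paste(x$seq$monomers, collapse = ""), x$n_conformations, nrow(x$nA),
    100 * x$acceptance_rate, x$layers_used))
  invisible(x)
}

#' Construct an ensemble from explicit occupancy tables
#'
#' Used for toy problems and oracles where conformations are written by hand.
#'
#' @param nA,nG integer matrices (conformations x layers) of per-layer A and
#'   G occupancies.
#' @param m multiplicities (default all 1).
#' @param n_layers grid size the occupancies refer to (default `ncol(nA)`).
#' @param dz layer width, nm.
#' @return a `conformation_ensemble`.
#' @export
manual_ensemble <- function(nA, nG, m = rep(1, nrow(nA)),
                            n_layers = ncol(nA), dz = 0.3) {
  nA <- as.matrix(nA); nG <- as.matrix(nG)
  stopifnot(all(dim(nA) == dim(nG)), nrow(nA) >= 1, all(nA >= 0), all(nG >= 0),
            length(m) == nrow(nA), n_layers >= ncol(nA))
  nper <- rowSums(nA) + rowSums(nG)
  if (length(unique(nper)) != 1)
    stop("all conformations must contain the same number of monomers")
  structure(list(
    nA = nA, nG = nG, m = as.numeric(m),
    n_conformations = sum(m), acceptance_rate = 1,
    layers_used = ncol(nA), n_layers = as.integer(n_layers), dz = dz,
    seq = NULL, geometry = NULL, rotations_per_state = NA, seed = NA
  ), class = "conformation_ensemble")
}

#' Write an ensemble cache file (plain text, bit-exact round trip)
#'
#' One row per (unique conformation, occupied layer) with integer counts and
#' the multiplicity, preceded by a header block recording the generation
#' parameters.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param path output file.
#' @export
write_ensemble <- function(ensemble, path) {
  hdr <- c(
    "# brushscft ensemble cache v1",
    sprintf("# sequence: %s", paste(ensemble$seq$monomers, collapse = "")),
    sprintf("# bond_length: %.17g", ensemble$geometry$bond_length),
    sprintf("# bond_angle: %.17g", ensemble$geometry$bond_angle),
    sprintf("# dihedral_states: %s",
            paste(sprintf("%.17g", ensemble$geometry$dihedral_states), collapse = " ")),
    sprintf("# first_monomer_z: %.17g", ensemble$geometry$first_monomer_z),
    sprintf("# n_layers: %d", ensemble$n_layers),
    sprintf("# dz: %.17g", ensemble$dz),
    sprintf("# layers_used: %d", ensemble$layers_used),
    sprintf("# rotations_per_state: %d", ensemble$rotations_per_state),
    sprintf("# seed: %.17g", as.numeric(ensemble$seed)),
    sprintf("# n_conformations: %d", ensemble$n_conformations),
    sprintf("# acceptance_rate: %.17g", ensemble$acceptance_rate),
    "conf\tlayer\tn_A\tn_G\tmultiplicity"
  )
  occ <- which(ensemble$nA + ensemble$nG > 0, arr.ind = TRUE)
  occ <- occ[order(occ[, 1], occ[, 2]), , drop = FALSE]
  rows <- sprintf("%d\t%d\t%d\t%d\t%d",
                  occ[, 1], occ[, 2],
                  ensemble$nA[occ], ensemble$nG[occ],
                  ensemble$m[occ[, 1]])
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ensemble cache file written by [write_ensemble()]
#'
#' @param path cache file path.
#' @return a `conformation_ensemble`.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s: ", key), "", grep(sprintf("^# %s:", key), hdr, value = TRUE))
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE, sep = "\t")
  nuniq <- max(tab$conf)
  Lc <- as.integer(get("layers_used"))
  nA <- matrix(0L, nuniq, Lc); nG <- matrix(0L, nuniq, Lc)
  idx <- cbind(tab$conf, tab$layer)
  nA[idx] <- tab$n_A; nG[idx] <- tab$n_G
  m <- numeric(nuniq)
  m[tab$conf] <- tab$multiplicity
  letters_seq <- strsplit(get("sequence"), "")[[1]]
  seq <- structure(list(monomers = letters_seq, grafted_index = 1L,
                        n = length(letters_seq), spec = get("sequence")),
                   class = "chain_sequence")
  geometry <- chain_geometry(
    bond_length = as.numeric(get("bond_length")),
    bond_angle = as.numeric(get("bond_angle")),
    dihedral_states = as.numeric(strsplit(get("dihedral_states"), " ")[[1]]),
    first_monomer_z = as.numeric(get("first_monomer_z"))
  )
  structure(list(
    nA = nA, nG = nG, m = m,
    n_conformations = as.integer(get("n_conformations")),
    acceptance_rate = as.numeric(get("acceptance_rate")),
    layers_used = Lc,
    n_layers = as.integer(get("n_layers")), dz = as.numeric(get("dz")),
    seq = seq, geometry = geometry,
    rotations_per_state = as.integer(get("rotations_per_state")),
    seed = as.numeric(get("seed"))
  ), class = "conformation_ensemble")
}
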