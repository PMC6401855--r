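# Chain sequences and coarse-grained chain geometry.

#' Build a chain sequence from a compact string
#'
#' Grammar: concatenated blocks `<M><n>` (e.g. `"A6G6"`, `"A1"`) and/or
#' parenthesised repeats `(<M><M>...)<n>` (e.g. `"(AG)6"`). Monomer letters
#' are A (adenine) and G (guanine). The first monomer in the expanded list is
#' the surface-grafted end.
#'
#' @param spec compact sequence string.
#' @return object of class `chain_sequence`: `monomers` (character vector),
#'   `grafted_index` (always 1, the first monomer), `n`.
#' @export
#' @examples
#' build_sequence("A6G6")
#' build_sequence("(AG)6")
build_sequence <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1, nzchar(spec))
  rest <- spec
  monomers <- character(0)
  token <- "^(?:\\(([A-Za-z]+)\\)|([A-Za-z]))([0-9]+)"
  while (nzchar(rest)) {
    m <- regexpr(token, rest, perl = TRUE)
    if (m == -1)
      stop("unrecognized sequence syntax near '", rest, "'")
    st <- attr(m, "capture.start")[1, ]
    len <- attr(m, "capture.length")[1, ]
    unit <- if (len[1] > 0) substr(rest, st[1], st[1] + len[1] - 1)
            else substr(rest, st[2], st[2] + len[2] - 1)
    count <- as.integer(substr(rest, st[3], st[3] + len[3] - 1))
    letters_unit <- strsplit(unit, "")[[1]]
    bad <- setdiff(unique(letters_unit), c("A", "G"))
    if (length(bad))
      stop("unrecognized monomer letter(s): ", paste(bad, collapse = ", "))
    monomers <- c(monomers, rep(letters_unit, count))
    rest <- substr(rest, attr(m, "match.length") + 1, nchar(rest))
  }
  if (length(monomers) == 0)
    stop("sequence '", spec, "' expands to zero monomers")
  structure(list(monomers = monomers, grafted_index = 1L,
                 n = length(monomers), spec = spec),
            class = "chain_sequence")
}

#' @export
print.chain_sequence <- function(x, ...) {
  cat("chain_sequence:", paste(x$monomers, collapse = ""),
      sprintf("(N = %d, grafted end = %s)\n", x$n, x$monomers[1]))
  invisible(x)
}

#' Coarse-grained chain geometry for the RIS model
#'
#' One bead per nucleotide connected by virtual bonds. The bond angle is the
#' internal angle at each bead (180 degrees = straight chain); each interior
#' torsion takes one of three rotational isomeric states. The numeric values
#' are model choices, not measured quantities: 0.6 nm is the order of the
#' ssDNA P-P virtual bond, 112 degrees and trans/gauche+/gauche- torsions of
#' 180/+60/-60 degrees are standard RIS conventions.
#'
#' @param bond_length virtual bond length, nm.
#' @param bond_angle internal bond angle, degrees.
#' @param dihedral_states the three torsion values (degrees), named
#'   trans/gauche_plus/gauche_minus.
#' @param first_monomer_z height of the grafted monomer centre above the
#'   surface, nm; `NULL` means half a layer width (set when an ensemble is
#'   generated).
#' @return object of class `chain_geometry`.
#' @export
chain_geometry <- function(bond_length = 0.6, bond_angle = 112,
                           dihedral_states = c(trans = 180,
                                               gauche_plus = 60,
                                               gauche_minus = -60),
                           first_monomer_z = NULL) {
  stopifnot(bond_length > 0, bond_angle > 0, bond_angle <= 180,
            length(dihedral_states) == 3)
  if (!is.null(first_monomer_z)) stopifnot(first_monomer_z >= 0)
  structure(list(bond_length = bond_length, bond_angle = bond_angle,
                 dihedral_states = dihedral_states,
                 first_monomer_z = first_monomer_z,
                 wall_mode = "reject"),
            class = "chain_geometry")
}

#' Discretization grid normal to the grafting surface
#'
#' @param n_layers number of layers (default 100).
#' @param dz layer width, nm (default 0.3).
#' @return object of class `scft_grid` with layer centres `z`.
#' @export
scft_grid <- function(n_layers = 100, dz = 0.3) {
  stopifnot(n_layers >= 3, dz > 0)
  structure(list(n_layers = as.integer(n_layers), dz = dz,
                 z = (seq_len(n_layers) - 0.5) * dz),
            class = "scft_grid")
}
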