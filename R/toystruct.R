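# Toy dimer/complex coordinate fixtures.  Residues are pseudo-residues (a
# Calpha and a Cbeta-like sidecain atom) strung along widely separated
# lines, so that all cross-chain distances are known by construction; chosen
# interface contacts are implanted at cutoff - 0.1 Angstrom and everything
# else stays beyond cutoff + 1.

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz, element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, formatC(paste0(" ", name), width = -4), resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

res_spacing <- 20  # Angstrom between consecutive pseudo-residues

#' Generate a toy two-chain dimer (optionally with partner chains)
#'
#' Chains `A` and `B` run along parallel lines 40 Angstrom apart (residue
#' spacing 20 Angstrom), so no cross-chain heavy-atom pair is closer than
#' `cutoff + 1` by construction.  For every pair `(i, j)` in
#' `interface_pairs`, a pseudo-sidechain atom is added to residue `i` of
#' chain `A` at exactly `cutoff - 0.1` Angstrom from the Calpha of residue
#' `j` of chain `B`.  Optional partner chains (for cross-model interface
#' fixtures) are placed along further axes, each contacting the listed
#' chain-A residues at `cutoff - 0.1`.  A `hydrogen_pair` adds a
#' hydrogen-only contact to test the heavy-atom rule.
#'
#' @param n_residues_per_chain Residues per chain.
#' @param interface_pairs Two-column matrix (or list of length-2 vectors) of
#'   residue index pairs (chain A index, chain B index).
#' @param cutoff Interface cutoff in Angstrom the fixture is built around.
#' @param seed Unused randomness guard (construction is deterministic); kept
#'   for interface uniformity.
#' @param file Output PDB path.
#' @param sequence Optional character vector of one-letter codes (length
#'   `n_residues_per_chain`) used as residue names on chains A and B;
#'   default all-alanine.
#' @param partner_contacts Optional named list: partner chain id ->
#'   integer vector of chain-A residues it contacts (e.g.,
#'   `list(C = 2L, S = 9L)`).
#' @param hydrogen_pair Optional length-2 integer vector `(i, j)`: residue
#'   `i` of chain A gets a hydrogen atom within the cutoff of residue `j`
#'   of chain B (heavy atoms of that pair stay far apart).
#' @return Invisibly, the output path.  Attribute `"truth"` records the
#'   constructed contacts.
#' @export
gen_toy_dimer <- function(n_residues_per_chain, interface_pairs = NULL,
                          cutoff = 5, seed = 1,
                          file = tempfile(fileext = ".pdb"),
                          sequence = NULL, partner_contacts = NULL,
                          hydrogen_pair = NULL) {
  n <- as.integer(n_residues_per_chain)
  if (n < 1) stop_pe("fixture_error", "need at least one residue per chain")
  if (is.list(interface_pairs))
    interface_pairs <- do.call(rbind, interface_pairs)
  if (!is.null(interface_pairs) && length(interface_pairs)) {
    interface_pairs <- matrix(as.integer(interface_pairs), ncol = 2)
    if (any(interface_pairs < 1) || any(interface_pairs > n))
      stop_pe("fixture_error", "interface pair indices outside chain length")
  } else interface_pairs <- matrix(integer(), ncol = 2)
  if (is.null(sequence)) sequence <- rep("A", n)
  if (length(sequence) != n || !all(sequence %in% AA_CODES))
    stop_pe("fixture_error", "sequence must be %d one-letter codes", n)
  resnames <- AA3_CODES[sequence]
  d_contact <- cutoff - 0.1

  lines <- character()
  serial <- 0L
  emit <- function(name, resid, chain, resno, xyz, element) {
    serial <<- serial + 1L
    lines <<- c(lines, pdb_atom_line(serial, name, resid, chain, resno,
                                     xyz, element))
  }
  # chain A along y = 0, chain B along y = 40 (sidechains pointing away)
  for (i in seq_len(n)) {
    emit("CA", resnames[i], "A", i, c(res_spacing * i, 0, 0), "C")
    emit("CB", resnames[i], "A", i, c(res_spacing * i, -3, 0), "C")
  }
  # implanted A->B contacts
  if (nrow(interface_pairs)) {
    for (r in seq_len(nrow(interface_pairs))) {
      i <- interface_pairs[r, 1]
      j <- interface_pairs[r, 2]
      emit(sprintf("G%d", r %% 10), resnames[i], "A", i,
           c(res_spacing * j, 40 - d_contact, 0), "C")
    }
  }
  if (!is.null(hydrogen_pair)) {
    i <- hydrogen_pair[1]
    j <- hydrogen_pair[2]
    emit("H1", resnames[i], "A", i,
         c(res_spacing * j, 40 - d_contact, 0.5), "H")
  }
  for (i in seq_len(n)) {
    emit("CA", resnames[i], "B", i, c(res_spacing * i, 40, 0), "C")
    emit("CB", resnames[i], "B", i, c(res_spacing * i, 43, 0), "C")
  }
  # partner chains along z axes, contacting chain A residues
  if (!is.null(partner_contacts)) {
    axes <- list(c(0, 0, 1), c(0, 0, -1), c(0, -1, 0))
    if (length(partner_contacts) > length(axes))
      stop_pe("fixture_error", "at most %d partner chains", length(axes))
    for (pi in seq_along(partner_contacts)) {
      pc <- names(partner_contacts)[pi]
      ax <- axes[[pi]]
      for (i in seq_len(n)) {
        emit("CA", "GLY", pc, i, res_spacing * i * c(1, 0, 0) + 40 * ax, "C")
      }
      touched <- as.integer(partner_contacts[[pi]])
      if (any(touched < 1 | touched > n))
        stop_pe("fixture_error", "partner contact indices outside chain")
      for (i in touched) {
        emit("CG", "GLY", pc, i,
             res_spacing * i * c(1, 0, 0) + d_contact * ax, "C")
      }
    }
  }
  writeLines(c(lines, "END"), file)
  truth <- list(interface_pairs = interface_pairs,
                partner_contacts = partner_contacts,
                hydrogen_pair = hydrogen_pair, cutoff = cutoff, n = n)
  attr(file, "truth") <- truth
  invisible(file)
}
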