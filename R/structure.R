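# Structure handling: coordinate reading, rigid superposition (Kabsch),
# heavy-atom interface detection and nearest-Calpha subdomain transfer.
# Residue sets are represented as character keys "chain:resno".

DEFAULT_MODIFIED_RESIDUES <- c(KCX = "LYS", MSE = "MET", CSO = "CYS",
                               SEP = "SER", TPO = "THR", PTR = "TYR",
                               MLY = "LYS", HYP = "PRO")

res_key <- function(chain, resno) {
  if (length(chain) == 0 || length(resno) == 0) return(character(0))
  paste0(chain, ":", resno)
}

key_resno <- function(keys) as.integer(sub("^[^:]*:", "", keys))

key_chain <- function(keys) sub(":.*$", "", keys)

#' Read a protein structure from a PDB file
#'
#' `ATOM` records are loaded; `HETATM` ligands, ions and solvent are
#' dropped, except records whose residue name appears in `modified_map`,
#' which are renamed to their parent residue and kept.
#'
#' @param path PDB file.
#' @param modified_map Named character vector mapping modified residue names
#'   to parent names (default covers common cases, e.g. carboxylated lysine
#'   `KCX` -> `LYS`).
#' @return Object of class `structure_model`: data.frame of atoms with
#'   columns `chain`, `resno`, `resid`, `atom`, `element`, `x`, `y`, `z`.
#' @export
read_structure <- function(path, modified_map = DEFAULT_MODIFIED_RESIDUES) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop_pe("format_error", "cannot parse '%s': %s", path,
                            conditionMessage(e)))
  at <- pdb$atom
  keep <- at$type == "ATOM" |
    (at$type == "HETATM" & at$resid %in% names(modified_map))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    stop_pe("format_error", "no usable ATOM records in '%s'", path)
  ren <- at$resid %in% names(modified_map)
  at$resid[ren] <- modified_map[at$resid[ren]]
  el <- at$elesy
  missing_el <- is.na(el) | el == ""
  if (any(missing_el)) {
    # fall back on the first letter of the atom name
    guess <- toupper(substr(gsub("[0-9 ]", "", at$elety[missing_el]), 1, 1))
    el[missing_el] <- guess
  }
  m <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                  atom = at$elety, element = toupper(el),
                  x = at$x, y = at$y, z = at$z,
                  stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(m[, c("x", "y", "z")]))))
    stop_pe("format_error", "non-finite coordinates in '%s'", path)
  class(m) <- c("structure_model", class(m))
  m
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model: %d atoms, chains %s>\n", nrow(x),
              paste(unique(x$chain), collapse = " ")))
  invisible(x)
}

#' Restrict a structure to one catalytic dimer
#'
#' @param model A [read_structure()] model.
#' @param chain_ids Character vector of exactly two chain ids.
#' @return The model restricted to those chains.
#' @export
extract_dimer <- function(model, chain_ids) {
  if (length(chain_ids) != 2)
    stop_pe("input_error", "chain_ids must name exactly two chains")
  missing <- setdiff(chain_ids, unique(model$chain))
  if (length(missing))
    stop_pe("input_error", "chains not in structure: %s",
            paste(missing, collapse = " "))
  out <- model[model$chain %in% chain_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

heavy_atoms <- function(model) model[!model$element %in% c("H", "D"), ,
                                     drop = FALSE]

atom_xyz <- function(model) as.matrix(model[, c("x", "y", "z")])

# Calpha coordinates, one row per residue, rownames "chain:resno".
ca_xyz <- function(model, chains = NULL) {
  m <- model[model$atom == "CA", , drop = FALSE]
  if (!is.null(chains)) m <- m[m$chain %in% chains, , drop = FALSE]
  xyz <- atom_xyz(m)
  rownames(xyz) <- res_key(m$chain, m$resno)
  xyz[!duplicated(rownames(xyz)), , drop = FALSE]
}

#' All residues of a structure (optionally one chain) as "chain:resno" keys
#' @param model A `structure_model`.
#' @param chains Optional chain filter.
#' @export
residue_keys <- function(model, chains = NULL) {
  m <- if (is.null(chains)) model else
    model[model$chain %in% chains, , drop = FALSE]
  unique(res_key(m$chain, m$resno))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation (proper, reflection excluded) and translation
#' minimizing the Calpha RMSD of `mobile` onto `reference` over the given
#' residue pairing.
#'
#' @param mobile,reference `structure_model`s.
#' @param residue_pairing Two-column character matrix (or data.frame) of
#'   residue keys `"chain:resno"`: column 1 in `mobile`, column 2 in
#'   `reference`.  Default pairs residues with identical keys.
#' @return Object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd`, `n_pairs`.  Apply with
#'   [apply_transform()].
#' @export
superimpose <- function(mobile, reference, residue_pairing = NULL) {
  cm <- ca_xyz(mobile)
  cr <- ca_xyz(reference)
  if (is.null(residue_pairing)) {
    shared <- intersect(rownames(cm), rownames(cr))
    residue_pairing <- cbind(shared, shared)
  }
  residue_pairing <- as.matrix(residue_pairing)
  ok <- residue_pairing[, 1] %in% rownames(cm) &
        residue_pairing[, 2] %in% rownames(cr)
  residue_pairing <- residue_pairing[ok, , drop = FALSE]
  X <- cm[residue_pairing[, 1], , drop = FALSE]
  Y <- cr[residue_pairing[, 2], , drop = FALSE]
  if (nrow(X) < 3)
    stop_pe("geometry_error", "need >= 3 paired Calpha atoms")
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  if (svd(Xc)$d[2] < 1e-8 * max(svd(Xc)$d[1], 1))
    stop_pe("geometry_error", "paired Calpha atoms are collinear")
  C <- crossprod(Xc, Yc)
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  out <- list(rotation = R, translation = as.numeric(my - R %*% mx),
              rmsd = rmsd, n_pairs = nrow(X))
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d pairs, RMSD %.4f A>\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a structure
#' @param model A `structure_model`.
#' @param sup A [superimpose()] result.
#' @return The transformed model.
#' @export
apply_transform <- function(model, sup) {
  xyz <- atom_xyz(model) %*% t(sup$rotation)
  xyz <- sweep(xyz, 2, sup$translation, "+")
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}

# Minimum heavy-atom distance per residue of set A against all atoms of set
# B; returns named vector (keys of A).
min_dist_per_residue <- function(atoms_a, atoms_b) {
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0)
    return(setNames(numeric(0), character(0)))
  A <- atom_xyz(atoms_a)
  B <- atom_xyz(atoms_b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  dmin_atom <- do.call(pmin, as.data.frame(d2))
  keys <- res_key(atoms_a$chain, atoms_a$resno)
  sqrt(tapply(dmin_atom, keys, min))
}

subset_residues <- function(model, keys) {
  model[res_key(model$chain, model$resno) %in% keys, , drop = FALSE]
}

#' Residues of one side at an interface (strict heavy-atom cutoff)
#'
#' A residue of `side_a` is at the interface iff any of its non-hydrogen
#' atoms lies strictly within `cutoff` of any non-hydrogen atom of
#' `side_b`.
#'
#' @param model A `structure_model`.
#' @param side_a,side_b Residue sets: chain id(s) or `"chain:resno"` keys;
#'   must be disjoint.
#' @param cutoff Distance cutoff in Angstrom (default 5, strict `<`).
#' @return Sorted character vector of `side_a` residue keys at the
#'   interface.
#' @export
interface_residues <- function(model, side_a, side_b, cutoff = 5) {
  ka <- resolve_residue_set(model, side_a)
  kb <- resolve_residue_set(model, side_b)
  if (length(intersect(ka, kb)))
    stop_pe("input_error", "interface sides must be disjoint")
  a <- heavy_atoms(subset_residues(model, ka))
  b <- heavy_atoms(subset_residues(model, kb))
  dmin <- min_dist_per_residue(a, b)
  sort_keys(names(dmin)[dmin < cutoff])
}

# chain ids ("A") or explicit keys ("A:12") -> keys
resolve_residue_set <- function(model, set) {
  if (length(set) == 0) return(character(0))
  is_key <- grepl(":", set)
  unique(c(set[is_key], residue_keys(model, set[!is_key])))
}

sort_keys <- function(keys) {
  keys[order(key_chain(keys), key_resno(keys))]
}

#' Interface of a query dimer against partner chains of a reference complex
#'
#' The query dimer is superimposed onto the catalytic dimer of the
#' reference complex (Kabsch over the residue pairing), and query residues
#' with any heavy atom strictly within `cutoff` of a heavy atom of the
#' reference's partner chains are returned.
#'
#' @param query_dimer A `structure_model` (two chains).
#' @param reference_complex A `structure_model` containing the reference
#'   dimer and its partner chains.
#' @param reference_partner_chains Chain ids of the partners (e.g., small
#'   subunits or neighboring large subunits).
#' @param pairing Residue pairing for [superimpose()] (query -> reference
#'   dimer); default pairs identical `"chain:resno"` keys.
#' @param cutoff Distance cutoff in Angstrom (strict `<`).
#' @return Sorted character vector of query residue keys.
#' @export
cross_model_interface <- function(query_dimer, reference_complex,
                                  reference_partner_chains,
                                  pairing = NULL, cutoff = 5) {
  if (length(reference_partner_chains) == 0) return(character(0))
  ref_dimer_chains <- setdiff(unique(reference_complex$chain),
                              reference_partner_chains)
  ref_dimer <- reference_complex[reference_complex$chain %in%
                                   ref_dimer_chains, , drop = FALSE]
  sup <- superimpose(query_dimer, ref_dimer, pairing)
  q <- heavy_atoms(apply_transform(query_dimer, sup))
  partners <- heavy_atoms(reference_complex[reference_complex$chain %in%
                                              reference_partner_chains, ,
                                            drop = FALSE])
  dmin <- min_dist_per_residue(q, partners)
  sort_keys(names(dmin)[dmin < cutoff])
}

#' Transfer a reference subdomain to a query by nearest Calpha
#'
#' After superimposing the query onto the reference, each residue of the
#' reference subdomain selects the query residue whose Calpha is nearest to
#' its own; ties go to the lower residue index.
#'
#' @param query,reference `structure_model`s.
#' @param reference_subdomain Residue keys (`"chain:resno"`) in the
#'   reference.
#' @param pairing Residue pairing for [superimpose()]; default identical
#'   keys.
#' @return Sorted unique character vector of query residue keys.
#' @export
subdomain_by_nearest_ca <- function(query, reference, reference_subdomain,
                                    pairing = NULL) {
  if (length(reference_subdomain) == 0) return(character(0))
  sup <- superimpose(query, reference, pairing)
  q <- apply_transform(query, sup)
  qca <- ca_xyz(q)
  rca <- ca_xyz(reference)
  missing <- setdiff(reference_subdomain, rownames(rca))
  if (length(missing)) {
    warning(sprintf("reference residues without Calpha skipped: %s",
                    paste(missing, collapse = " ")))
    reference_subdomain <- setdiff(reference_subdomain, missing)
  }
  # deterministic tie-break: order query residues by (chain, resno) and
  # take the first minimum
  ord <- order(key_chain(rownames(qca)), key_resno(rownames(qca)))
  qca <- qca[ord, , drop = FALSE]
  picked <- vapply(reference_subdomain, function(k) {
    d2 <- rowSums(sweep(qca, 2, rca[k, ])^2)
    rownames(qca)[which.min(d2)]
  }, character(1))
  sort_keys(unique(picked))
}

#' Residues near a core set (strict heavy-atom cutoff, core excluded)
#'
#' @param model A `structure_model`.
#' @param core_residues Residue keys of the core set (non-empty).
#' @param cutoff Distance cutoff in Angstrom (strict `<`).
#' @return Sorted character vector of residue keys with any heavy atom
#'   strictly within `cutoff` of a core heavy atom, excluding core members.
#' @export
near_set <- function(model, core_residues, cutoff = 5) {
  if (length(core_residues) == 0)
    stop_pe("input_error", "core set must be non-empty")
  if (cutoff <= 0) return(character(0))
  core <- heavy_atoms(subset_residues(model, core_residues))
  rest_keys <- setdiff(residue_keys(model), core_residues)
  rest <- heavy_atoms(subset_residues(model, rest_keys))
  dmin <- min_dist_per_residue(rest, core)
  sort_keys(names(dmin)[dmin < cutoff])
}

#' Map structure residues to alignment columns
#'
#' @param structure_sequence Character vector of one-letter codes (the
#'   chain's residues in order).
#' @param alignment_row Gapped character vector (one alignment row).
#' @param max_mismatch_fraction Mismatch tolerance between the ungapped row
#'   and the structure sequence (default 0.05).
#' @return data.frame with `residue_index`, `column`, `match` (logical
#'   flag; mismatched positions are mapped but flagged).
#' @export
map_residues_to_alignment <- function(structure_sequence, alignment_row,
                                      max_mismatch_fraction = 0.05) {
  cols <- which(alignment_row != GAP_CHAR)
  if (length(cols) == 0)
    stop_pe("mapping_error", "alignment row is all gaps")
  if (length(cols) != length(structure_sequence))
    stop_pe("mapping_error",
            "ungapped row length %d != structure length %d",
            length(cols), length(structure_sequence))
  match_flag <- alignment_row[cols] == structure_sequence
  if (mean(!match_flag) > max_mismatch_fraction)
    stop_pe("mapping_error", "mismatch fraction %.3f exceeds tolerance %.3f",
            mean(!match_flag), max_mismatch_fraction)
  data.frame(residue_index = seq_along(structure_sequence),
             column = cols, match = match_flag)
}
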