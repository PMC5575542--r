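# Self-contained fixture bundles: everything the pipeline consumes, written
# to disk with a JSON manifest, all contacts and truth tables known by
# construction.

#' Write a complete synthetic fixture bundle
#'
#' Generates a ladder tree, evolves an alignment under `config`, builds toy
#' dimer/complex coordinate files whose chain sequences match the first
#' alignment row and whose interface contacts are implanted at known
#' residues, and writes alignment (FASTA), tree (Newick), truth region
#' table (TSV), structures (PDB), true-ancestor and presence tables (TSV),
#' nested ancestor specs usable for five phylogenetic windows, and a JSON
#' manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param mean_branch_length Mean branch length of the generated tree.
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
gen_fixture_bundle <- function(config, out_dir, mean_branch_length = 0.2) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_pe("io_error", "cannot create directory '%s'", out_dir)
  tree <- gen_tree(config$n_leaves, "ladder", mean_branch_length,
                   seed = config$seed)
  ds <- evolve_alignment(tree, config)
  aln <- ds$alignment
  taxon1 <- rownames(aln)[1]
  row1 <- aln[1, ]
  nongap_cols <- which(row1 != GAP_CHAR)
  seq1 <- row1[nongap_cols]
  n_res <- length(seq1)
  if (n_res < 12)
    stop_pe("fixture_error", "first alignment row too gappy for structures")
  at <- function(frac) max(1L, min(n_res, as.integer(round(frac * n_res))))

  dimer_pairs <- cbind(c(at(0.2), at(0.5)), c(at(0.2), at(0.5)))
  ll_contact <- at(0.3)
  ls_contact <- at(0.7)
  f3_contact <- at(0.4)
  barrel <- at(0.55):at(0.6)
  loop6 <- at(0.62):at(0.64)
  nterm <- 1:2
  cterm <- (n_res - 1):n_res

  paths <- list(
    alignment = file.path(out_dir, "alignment.fasta"),
    tree = file.path(out_dir, "tree.nwk"),
    regions = file.path(out_dir, "regions_truth.tsv"),
    query = file.path(out_dir, "query_dimer.pdb"),
    formI = file.path(out_dir, "formI_reference.pdb"),
    formIII = file.path(out_dir, "formIII_reference.pdb"),
    ancestors = file.path(out_dir, "ancestors_true.tsv"),
    presence = file.path(out_dir, "presence_true.tsv"),
    manifest = file.path(out_dir, "manifest.json"))

  write_fasta(aln, paths$alignment)
  ape::write.tree(ds$tree, paths$tree)
  gen_toy_dimer(n_res, dimer_pairs, cutoff = 5, file = paths$query,
                sequence = seq1)
  gen_toy_dimer(n_res, dimer_pairs, cutoff = 5, file = paths$formI,
                sequence = seq1,
                partner_contacts = list(C = ll_contact, S = ls_contact))
  gen_toy_dimer(n_res, NULL, cutoff = 5, file = paths$formIII,
                sequence = seq1,
                partner_contacts = list(D = f3_contact))

  col_of <- function(res) nongap_cols[res]
  truth <- region_map(list(
    FormI_LL_interface = col_of(ll_contact),
    FormI_LS_interface = col_of(ls_contact),
    FormIII_LL_interface = col_of(f3_contact),
    dimer_interface = col_of(unique(dimer_pairs[, 1])),
    barrel_strands = col_of(barrel),
    near_barrel = integer(0),     # 20 A residue spacing: nothing nearby
    loop6 = col_of(loop6),
    N_terminal = col_of(nterm),
    C_terminal = col_of(cterm)),
    provenance = list(cutoff = 5, reference_row = taxon1))
  write_region_map(truth, paths$regions)

  anc_tab <- data.frame(node = names(ds$true_ancestors),
                        sequence = vapply(ds$true_ancestors, seq_string,
                                          character(1)))
  write.table(anc_tab, paths$ancestors, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pres_tab <- data.frame(node = names(ds$true_presence),
                         presence = vapply(ds$true_presence, function(p)
                           paste(as.integer(p), collapse = ""),
                           character(1)))
  write.table(pres_tab, paths$presence, sep = "\t", quote = FALSE,
              row.names = FALSE)

  n <- config$n_leaves
  ancestors <- setNames(
    lapply(seq_len(min(6, n - 1)), function(k)
      paste0("L", seq_len(n - k + 1))),
    paste0("anc", seq_len(min(6, n - 1))))
  subdomains <- list(barrel_strands = barrel, loop6 = loop6,
                     n_terminal = nterm, c_terminal = cterm)
  manifest <- list(seed = config$seed,
                   files = lapply(paths[names(paths) != "manifest"],
                                  basename),
                   config = unclass(config),
                   reference_row = taxon1,
                   ancestors = ancestors,
                   subdomains = subdomains)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
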