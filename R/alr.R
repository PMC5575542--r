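# Approximate likelihood-ratio branch support: the likelihood of the input
# resolution of an internal branch against the best of its two
# nearest-neighbor-interchange alternatives, with the five branch lengths
# adjacent to the interchange re-optimized for each resolution.  By
# time-reversibility the likelihood does not depend on root placement, so
# the three resolutions are evaluated on trees rooted (trifurcating) at the
# focal branch.

strip_semi <- function(s) sub(";$", "", s)

subtree_newick <- function(tree, id, len) {
  if (id <= ape::Ntip(tree))
    return(sprintf("%s:%.10g", tree$tip.label[id], len))
  cl <- ape::extract.clade(tree, id)
  sprintf("%s:%.10g", strip_semi(ape::write.tree(cl)), len)
}

# Optimize the five branches adjacent to the focal split (the two root
# halves collapse into the single central branch here because the root is
# trifurcating at the split).
optimize_local <- function(tree, aln, model, edge_ids, rounds = 2) {
  cur <- tree_log_likelihood(tree, aln, model)
  for (r in seq_len(rounds)) {
    for (e in edge_ids) {
      f <- function(x) {
        tr <- tree
        tr$edge.length[e] <- x
        tree_log_likelihood(tr, aln, model)
      }
      opt <- optimize(f, interval = c(1e-8, 20), maximum = TRUE, tol = 1e-6)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
  }
  cur
}

#' Approximate likelihood-ratio (aLR) support for an internal branch
#'
#' @param tree Rooted binary `phylo` with branch lengths and internal labels.
#' @param aln A [protein_alignment()].
#' @param model An [aa_model()].
#' @param branch Label of the internal node below the focal branch (the
#'   branch is the edge between that node and its parent).  Pendant
#'   branches (and branches pendant in the unrooted sense) are rejected.
#' @param rounds Local optimization sweeps per resolution.
#' @return List of class `branch_support`: `branch`, `aLR` (ratio, may be
#'   `Inf`), `log10_aLR`, and `lnL` (named vector: input resolution and the
#'   two NNI alternatives).
#' @export
branch_aLR <- function(tree, aln, model, branch, rounds = 2) {
  tree <- ensure_node_labels(tree)
  v <- node_id(tree, branch)
  n <- ape::Ntip(tree)
  if (v <= n)
    stop_pe("invalid_argument", "'%s' is a pendant branch", branch)
  v_children <- tree$edge[tree$edge[, 1] == v, 2]
  if (length(v_children) != 2)
    stop_pe("invalid_argument", "focal node must be binary")
  child_labs <- node_label(tree, v_children)

  ut <- ape::unroot(tree)
  vu <- node_id(ut, branch)
  ru <- ape::root(ut, node = vu)
  ru <- ape::reorder.phylo(ru, "cladewise")
  rn <- ape::Ntip(ru) + 1L
  rkids <- ru$edge[ru$edge[, 1] == rn, 2]
  rkid_labs <- node_label(ru, rkids)
  if (length(rkids) != 3)
    stop_pe("invalid_argument", "cannot form a quartet around '%s'", branch)
  ab <- rkids[match(child_labs, rkid_labs)]
  w <- setdiff(rkids, ab)
  if (length(w) != 1 || any(is.na(ab)))
    stop_pe("invalid_argument", "cannot identify quartet around '%s'", branch)
  if (w <= ape::Ntip(ru))
    stop_pe("invalid_argument",
            "branch '%s' is pendant in the unrooted tree", branch)
  wkids <- ru$edge[ru$edge[, 1] == w, 2]
  if (length(wkids) != 2)
    stop_pe("invalid_argument", "cannot form a quartet around '%s'", branch)

  elen <- function(node) ru$edge.length[match(node, ru$edge[, 2])]
  A <- subtree_newick(ru, ab[1], elen(ab[1]))
  B <- subtree_newick(ru, ab[2], elen(ab[2]))
  C <- subtree_newick(ru, wkids[1], elen(wkids[1]))
  D <- subtree_newick(ru, wkids[2], elen(wkids[2]))
  t0 <- elen(w)

  eval_res <- function(x1, x2, y1, y2) {
    nwk <- sprintf("((%s,%s)focalsplit:%.10g,%s,%s);", x1, x2, t0, y1, y2)
    tr <- ape::read.tree(text = nwk)
    rt <- ape::Ntip(tr) + 1L
    cherry <- rt + match("focalsplit", tr$node.label) - 1L
    local <- which(tr$edge[, 1] %in% c(rt, cherry))
    optimize_local(tr, aln, model, local, rounds = rounds)
  }
  ll_in <- eval_res(A, B, C, D)
  ll_n1 <- eval_res(A, C, B, D)
  ll_n2 <- eval_res(A, D, B, C)
  dl <- ll_in - max(ll_n1, ll_n2)
  out <- list(branch = branch, aLR = exp(dl), log10_aLR = dl / log(10),
              lnL = c(input = ll_in, nni1 = ll_n1, nni2 = ll_n2))
  class(out) <- "branch_support"
  out
}

#' @export
print.branch_support <- function(x, ...) {
  cat(sprintf("<branch_support %s: aLR = %.4g (log10 = %.3f)>\n",
              x$branch, x$aLR, x$log10_aLR))
  invisible(x)
}
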