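# Fitch parsimony for binary presence/absence (indel) characters, each
# alignment column treated independently.

#' Fitch parsimony reconstruction of site presence at ancestors
#'
#' Classic two-pass Fitch: the up-pass takes the intersection of the child
#' state sets where non-empty, otherwise their union (counting one change);
#' the down-pass resolves ambiguity by preferring the parent's state, and
#' root ambiguity resolves to `root_ambiguous` (default `"present"`).  The
#' total number of changes per column equals the parsimony minimum.
#'
#' @param tree Rooted binary `phylo` (internal labels auto-assigned).
#' @param presence_matrix Logical (or `{0,1}`) matrix, taxa x columns:
#'   `TRUE`/1 = residue present, `FALSE`/0 = gap.  Rownames must cover the
#'   tree's tips.
#' @param root_ambiguous `"present"` or `"absent"`.
#' @return List with `presence` (logical matrix, internal node labels x
#'   columns) and `changes` (integer vector of per-column minimum change
#'   counts).
#' @export
fitch_indel_reconstruction <- function(tree, presence_matrix,
                                       root_ambiguous = c("present", "absent")) {
  root_ambiguous <- match.arg(root_ambiguous)
  tree <- ensure_node_labels(tree)
  if (!all(tree$tip.label %in% rownames(presence_matrix)))
    stop_pe("input_error", "presence matrix missing taxa: %s",
            paste(setdiff(tree$tip.label, rownames(presence_matrix)),
                  collapse = " "))
  pm <- presence_matrix[tree$tip.label, , drop = FALSE]
  storage.mode(pm) <- "logical"
  ptree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(ptree)
  nn <- n + ptree$Nnode
  root <- n + 1L
  L <- ncol(pm)
  parent <- ptree$edge[, 1]
  child <- ptree$edge[, 2]

  # Bit encoding per node x column: 1 = present, 2 = absent, 3 = ambiguous.
  state <- matrix(0L, nn, L)
  state[seq_len(n), ] <- ifelse(pm, 1L, 2L)
  changes <- integer(L)
  # Up-pass: accumulate intersections; where empty, take union + 1 change.
  acc <- vector("list", nn)
  for (i in seq_along(parent)) {
    u <- parent[i]
    v <- child[i]
    sv <- state[v, ]
    if (is.null(acc[[u]])) {
      acc[[u]] <- sv
    } else {
      inter <- bitwAnd(acc[[u]], sv)
      un <- bitwOr(acc[[u]], sv)
      empty <- inter == 0L
      changes <- changes + empty
      acc[[u]] <- ifelse(empty, un, inter)
    }
    state[u, ] <- acc[[u]]
  }
  # Down-pass
  res <- matrix(NA, ptree$Nnode, L)
  rownames(res) <- ptree$node.label
  sr <- state[root, ]
  sr[sr == 3L] <- if (root_ambiguous == "present") 1L else 2L
  final <- matrix(0L, nn, L)
  final[root, ] <- sr
  for (i in rev(seq_along(parent))) {
    u <- parent[i]
    v <- child[i]
    sv <- state[v, ]
    fu <- final[u, ]
    take_parent <- bitwAnd(sv, fu) != 0L
    resolved <- ifelse(take_parent, fu, sv)
    # remaining ambiguity (set = {present, absent}, parent not in set:
    # impossible; but guard): resolve to present
    resolved[resolved == 3L] <- 1L
    final[v, ] <- resolved
  }
  for (v in (root):nn) res[v - n, ] <- final[v, ] == 1L
  list(presence = res, changes = changes)
}
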