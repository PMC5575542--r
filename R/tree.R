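# Tree construction and manipulation (ape::phylo throughout).

# Deterministic internal labels: node number n+1 (the root) becomes "N1",
# n+2 -> "N2", ...  Existing labels are kept.
ensure_node_labels <- function(tree) {
  n <- ape::Ntip(tree)
  lbl <- tree$node.label
  if (is.null(lbl)) lbl <- rep("", tree$Nnode)
  empty <- is.na(lbl) | lbl == ""
  lbl[empty] <- paste0("N", which(empty))
  tree$node.label <- lbl
  tree
}

node_id <- function(tree, label) {
  n <- ape::Ntip(tree)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (is.na(j)) stop_pe("input_error", "no node named '%s' in tree", label)
  n + j
}

node_label <- function(tree, id) {
  n <- ape::Ntip(tree)
  out <- character(length(id))
  tip <- id <= n
  out[tip] <- tree$tip.label[id[tip]]
  out[!tip] <- tree$node.label[id[!tip] - n]
  out
}

# All node ids (tips and internals) in the clade rooted at `id`, inclusive.
clade_ids <- function(tree, id) {
  kids <- tree$edge[tree$edge[, 1] == id, 2]
  if (length(kids) == 0) return(id)
  c(id, unlist(lapply(kids, clade_ids, tree = tree)))
}

#' Generate a random or regular rooted binary tree
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param mode `"yule"` (random topology by uniform leaf splitting),
#'   `"ladder"` (caterpillar) or `"balanced"` (recursive halving).
#' @param mean_branch_length Branch lengths are drawn i.i.d. exponential
#'   with this mean (all positive).
#' @param seed Integer seed; identical seeds give identical trees.
#' @return Rooted binary `phylo` with leaves `L1..Ln` and internal labels
#'   `N1..N(n-1)` (root = `N1`).
#' @export
gen_tree <- function(n_leaves, mode = c("yule", "ladder", "balanced"),
                     mean_branch_length = 0.1, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n_leaves) || n_leaves < 2)
    stop_pe("invalid_argument", "n_leaves must be >= 2")
  n <- as.integer(n_leaves)
  with_seed(seed, {
    topo <- switch(mode,
      ladder = {
        s <- "(L1,L2)"
        for (i in seq_len(n - 2) + 2L) s <- sprintf("(%s,L%d)", s, i)
        s
      },
      balanced = {
        bal <- function(idx) {
          if (length(idx) == 1) return(paste0("L", idx))
          h <- ceiling(length(idx) / 2)
          sprintf("(%s,%s)", bal(idx[seq_len(h)]), bal(idx[-seq_len(h)]))
        }
        bal(seq_len(n))
      },
      yule = {
        # Growing-tree process: repeatedly bifurcate a uniformly chosen leaf.
        s <- "(L1,L2)"
        for (i in seq_len(n - 2) + 2L) {
          pick <- sample.int(i - 1L, 1)
          s <- sub(sprintf("\\bL%d\\b", pick),
                   sprintf("(L%d,L%d)", pick, i), s)
        }
        s
      })
    tree <- ape::read.tree(text = paste0(topo, ";"))
    tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / mean_branch_length)
    ensure_node_labels(tree)
  })
}

#' Root a tree on the branch separating an outgroup from the ingroup
#'
#' The root is placed at the midpoint of the branch between the outgroup
#' (a single leaf, or a clade in the unrooted sense) and the rest of the
#' tree.
#'
#' @param tree A `phylo` (rooted or unrooted).
#' @param outgroup_taxa Character vector of tip labels.
#' @return Rooted binary `phylo` with internal labels filled in.
#' @export
root_with_outgroup <- function(tree, outgroup_taxa) {
  if (!all(outgroup_taxa %in% tree$tip.label))
    stop_pe("rooting_error", "outgroup taxa missing from tree: %s",
            paste(setdiff(outgroup_taxa, tree$tip.label), collapse = " "))
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  rooted <- tryCatch(
    ape::root(utree, outgroup = outgroup_taxa, resolve.root = TRUE),
    error = function(e) stop_pe("rooting_error", "cannot root: %s",
                                conditionMessage(e)))
  if (!ape::is.monophyletic(rooted, outgroup_taxa))
    stop_pe("rooting_error", "outgroup is not monophyletic in unrooted tree")
  # ape places the root unevenly on the split branch; rebalance the two
  # root-adjacent edges to equal halves of their total length.
  root <- ape::Ntip(rooted) + 1L
  re <- which(rooted$edge[, 1] == root)
  tot <- sum(rooted$edge.length[re])
  rooted$edge.length[re] <- tot / 2
  ensure_node_labels(rooted)
}
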