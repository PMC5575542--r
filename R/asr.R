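# Empirical-Bayes marginal ancestral reconstruction.
#
# For every internal node the posterior over the 20 amino acids at each site
# combines the partial likelihood of the subtree below the node with the
# "outside" likelihood of the rest of the tree, per gamma category; categories
# are then mixed with weights proportional to the per-site category
# likelihoods.  Site presence at ancestors is decided solely by Fitch
# parsimony on the gap pattern (see fitch_indel_reconstruction), not by the
# state posteriors.

#' Marginal ancestral posteriors and ML sequences for all internal nodes
#'
#' @param tree Rooted binary `phylo` with branch lengths; internal nodes are
#'   (auto-)labelled `N1..` with `N1` the root.
#' @param aln A [protein_alignment()].
#' @param model An [aa_model()].
#' @param root_ambiguous How Fitch root ambiguity for indel characters is
#'   resolved (`"present"` by default; see [fitch_indel_reconstruction()]).
#' @return Object of class `ancestral_reconstruction`: list with
#'   \describe{
#'     \item{tree}{the (labelled) input tree}
#'     \item{posteriors}{named list, node label -> 20 x L matrix `p` with
#'       `p[i, j]` the posterior of amino acid `i` at site `j` (columns sum
#'       to 1)}
#'     \item{presence}{named list, node label -> logical vector (Fitch
#'       reconstruction of site presence)}
#'     \item{ml}{named list, node label -> ML sequence (character vector,
#'       `"-"` at absent sites)}
#'     \item{max_posterior}{named list, node label -> per-site maximum
#'       posterior}
#'   }
#' @export
marginal_ancestral_posteriors <- function(tree, aln, model,
                                          root_ambiguous = "present") {
  tree <- ensure_node_labels(tree)
  if (!ape::is.rooted(tree))
    stop_pe("input_error", "tree must be rooted")
  pl <- peel_likelihood(tree, aln, model, keep = TRUE)
  ptree <- pl$tree
  n <- ape::Ntip(ptree)
  nn <- n + ptree$Nnode
  root <- n + 1L
  L <- ncol(aln)
  K <- model$K
  parent <- ptree$edge[, 1]
  child <- ptree$edge[, 2]
  children_of <- split(child, parent)

  internal_ids <- root:nn
  # per category: above-pass (preorder = reverse postorder edge order)
  post_by_cat <- vector("list", K)       # [[k]][[node]] = unnormalized post
  sitell_by_cat <- vector("list", K)     # [[k]][[node]] = per-site log-lik
  for (k in seq_len(K)) {
    ck <- pl$cats[[k]]
    above <- vector("list", nn)
    logsc_above <- numeric(nn)
    above[[root]] <- matrix(model$pi, 20, L)
    for (i in rev(seq_along(parent))) {
      u <- parent[i]
      v <- child[i]
      if (v <= n) next                   # tip posteriors not needed
      sibs <- setdiff(children_of[[as.character(u)]], v)
      out <- above[[u]]
      lsc <- logsc_above[u]
      for (w in sibs) {
        out <- out * ck$term[[w]]
        lsc <- lsc + ck$logsc[w]
      }
      av <- crossprod(ck$P[[v]], out)    # t(P) %*% outside
      mx <- max(av)
      if (mx > 0 && is.finite(mx)) {
        av <- av / mx
        lsc <- lsc + log(mx)
      }
      above[[v]] <- av
      logsc_above[v] <- lsc
    }
    post <- vector("list", nn)
    sll <- vector("list", nn)
    for (v in internal_ids) {
      m <- above[[v]] * ck$clm[[v]]
      tot <- colSums(m)
      post[[v]] <- m
      sll[[v]] <- log(tot) + logsc_above[v] + ck$logsc[v]
    }
    post_by_cat[[k]] <- post
    sitell_by_cat[[k]] <- sll
  }

  # Fitch presence from the gap pattern
  presence_leaves <- !is.na(pl$data_int)   # rows in ptree tip order
  rownames(presence_leaves) <- ptree$tip.label
  fitch <- fitch_indel_reconstruction(ptree, presence_leaves,
                                      root_ambiguous = root_ambiguous)

  posteriors <- list()
  presence <- list()
  ml <- list()
  maxp <- list()
  for (v in internal_ids) {
    lab <- node_label(ptree, v)
    # category weights per site: softmax of per-category site log-liks
    llmat <- do.call(rbind, lapply(sitell_by_cat, `[[`, v))  # K x L
    mx <- apply(llmat, 2, max)
    w <- exp(sweep(llmat, 2, mx, "-"))
    w <- sweep(w, 2, colSums(w), "/")
    pm <- matrix(0, 20, L, dimnames = list(AA_CODES, NULL))
    for (k in seq_len(K)) {
      pk <- post_by_cat[[k]][[v]]
      cs <- colSums(pk)
      cs[cs == 0] <- 1
      pm <- pm + sweep(pk, 2, cs, "/") * rep(w[k, ], each = 20)
    }
    pres <- fitch$presence[lab, ]
    all_gap <- colSums(presence_leaves) == 0
    pres[all_gap] <- FALSE               # posterior undefined, flag absent
    posteriors[[lab]] <- pm
    presence[[lab]] <- pres
    maxp[[lab]] <- col_max(pm)
  }
  recon <- structure(list(tree = ptree, posteriors = posteriors,
                          presence = presence, ml = NULL,
                          max_posterior = maxp,
                          indel_changes = fitch$changes),
                     class = "ancestral_reconstruction")
  recon$ml <- setNames(lapply(names(posteriors), function(nd)
    ml_ancestral_sequence(recon, nd)), names(posteriors))
  recon
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("<ancestral_reconstruction: %d internal nodes, %d sites>\n",
              length(x$posteriors), ncol(x$posteriors[[1]])))
  invisible(x)
}

#' Maximum-likelihood ancestral sequence at a node
#'
#' The amino acid with the highest posterior at every site; exact ties are
#' broken by alphabetical order of the one-letter code, and sites
#' reconstructed absent by the indel step emit `"-"`.
#'
#' @param recon An `ancestral_reconstruction`.
#' @param node Internal node label.
#' @return Character vector of length L.
#' @export
ml_ancestral_sequence <- function(recon, node) {
  p <- recon$posteriors[[node]]
  if (is.null(p))
    stop_pe("input_error", "node '%s' not reconstructed", node)
  alpha_order <- order(AA_CODES)         # indices of codes in alphabetical order
  p_alpha <- p[alpha_order, , drop = FALSE]
  pick <- apply(p_alpha, 2, which.max)   # first max in alphabetical order
  seq <- AA_CODES[alpha_order][pick]
  seq[!recon$presence[[node]]] <- GAP_CHAR
  seq
}

#' Distribution of per-site maximum posteriors over 10% bins
#'
#' Bins the maximum posterior of every present site into intervals
#' \[0, 0.1), ..., \[0.9, 1.0\] and returns the proportion of sites per bin.
#'
#' @param recon An `ancestral_reconstruction`.
#' @param node Internal node label.
#' @param bin_width Bin width (default 0.1).
#' @return Named numeric vector of proportions summing to 1.
#' @export
bin_posteriors <- function(recon, node, bin_width = 0.1) {
  x <- recon$max_posterior[[node]][recon$presence[[node]]]
  nb <- round(1 / bin_width)
  idx <- pmin(floor(x / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  lo <- (seq_len(nb) - 1) * bin_width
  names(counts) <- sprintf("[%.1f,%.1f%s", lo, lo + bin_width,
                           c(rep(")", nb - 1), "]"))
  counts / sum(counts)
}

#' Sample alternate ancestral sequences from the posterior
#'
#' Each present site is drawn independently from its posterior column;
#' absent sites emit `"-"`.
#'
#' @param recon An `ancestral_reconstruction`.
#' @param node Internal node label.
#' @param n Number of sampled sequences (default 5).
#' @param seed Integer seed for reproducibility.
#' @return Character matrix `n x L`; rows are the sampled sequences.
#' @export
sample_alternate_ancestors <- function(recon, node, n = 5, seed = NULL) {
  p <- recon$posteriors[[node]]
  if (is.null(p))
    stop_pe("input_error", "node '%s' not reconstructed", node)
  pres <- recon$presence[[node]]
  L <- ncol(p)
  with_seed(seed, {
    out <- matrix(GAP_CHAR, n, L)
    for (j in which(pres)) {
      out[, j] <- sample(AA_CODES, n, replace = TRUE, prob = p[, j])
    }
    out
  })
}
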