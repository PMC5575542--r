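# Felsenstein pruning under an amino-acid model with discrete-gamma rates.
# Gaps are missing data (all-ones partial likelihoods).  Numerical scaling is
# a single scalar per node (max of the partial-likelihood matrix), which is
# exact and sufficient to keep site likelihoods well inside double range.

# One-hot (or all-ones for gaps) 20 x L tip matrices.
tip_partials <- function(data_int) {
  L <- ncol(data_int)
  lapply(seq_len(nrow(data_int)), function(i) {
    m <- matrix(0, 20, L)
    s <- data_int[i, ]
    obs <- which(!is.na(s))
    m[cbind(s[obs], obs)] <- 1
    if (length(obs) < L) m[, setdiff(seq_len(L), obs)] <- 1
    m
  })
}

# Core post-order pass.  Returns, per gamma category: partial-likelihood
# matrices for every node, per-edge transition matrices (children keyed by
# node id), accumulated log scale factors, and the K x L matrix of per-site
# log-likelihoods conditional on each category.
peel_likelihood <- function(tree, aln, model, keep = FALSE) {
  if (!all(tree$tip.label %in% rownames(aln)))
    stop_pe("input_error", "tree tips missing from alignment: %s",
            paste(setdiff(tree$tip.label, rownames(aln)), collapse = " "))
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  root <- n + 1L
  L <- ncol(aln)
  data_int <- encode_alignment(aln)[tree$tip.label, , drop = FALSE]
  tips <- tip_partials(data_int)
  K <- model$K
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  elen <- tree$edge.length
  root_ll <- matrix(NA_real_, K, L)
  cats <- vector("list", K)
  for (k in seq_len(K)) {
    r <- model$rates[k]
    clm <- vector("list", nn)
    clm[seq_len(n)] <- tips
    logsc <- numeric(nn)
    Pmats <- if (keep) vector("list", nn) else NULL
    Tmats <- if (keep) vector("list", nn) else NULL
    acc <- vector("list", nn)
    finalize <- function(v) {
      m <- acc[[v]]
      mx <- max(m)
      if (mx > 0 && is.finite(mx)) {
        m <- m / mx
        logsc[v] <<- logsc[v] + log(mx)
      }
      clm[[v]] <<- m
    }
    for (i in seq_along(parent)) {
      u <- parent[i]
      v <- child[i]
      if (v > n && is.null(clm[[v]])) finalize(v)
      P <- transition_probs(model, elen[i], r)
      term <- P %*% clm[[v]]
      if (keep) {
        Pmats[[v]] <- P
        Tmats[[v]] <- term
      }
      acc[[u]] <- if (is.null(acc[[u]])) term else acc[[u]] * term
      logsc[u] <- logsc[u] + logsc[v]
    }
    finalize(root)
    root_ll[k, ] <- log(colSums(model$pi * clm[[root]])) + logsc[root]
    cats[[k]] <- if (keep)
      list(clm = clm, logsc = logsc, P = Pmats, term = Tmats) else NULL
  }
  list(tree = tree, root_ll = root_ll,
       cats = if (keep) cats else NULL, data_int = data_int)
}

#' Tree log-likelihood under an amino-acid model with discrete-gamma rates
#'
#' Sum over sites of the log of the category-averaged site likelihood,
#' computed by Felsenstein's pruning algorithm.  Gap symbols are treated as
#' missing data.
#'
#' @param tree Rooted `phylo` with branch lengths (substitutions/site).
#' @param aln A [protein_alignment()] containing all tree tips as rows.
#' @param model An [aa_model()].
#' @return Log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(tree, aln, model) {
  pl <- peel_likelihood(tree, aln, model)
  site_ll <- apply(pl$root_ll, 2, function(x) {
    m <- max(x)
    if (!is.finite(m)) return(-Inf)
    m + log(mean(exp(x - m)))
  })
  sum(site_ll)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise bounded 1-D maximization (golden-section via
#' [stats::optimize()]) of the tree log-likelihood over each branch length
#' on \[1e-8, 20\], repeated until a full sweep improves the log-likelihood
#' by less than `tol`.
#'
#' @param tree Rooted `phylo` (topology fixed).
#' @param aln A [protein_alignment()].
#' @param model An [aa_model()].
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_rounds Maximum number of sweeps over all branches.
#' @return The tree with optimized `edge.length`; attribute `"logLik"`
#'   carries the final log-likelihood (always >= the input tree's).
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_rounds = 20) {
  cur <- tree_log_likelihood(tree, aln, model)
  for (round in seq_len(max_rounds)) {
    start <- cur
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tr <- tree
        tr$edge.length[e] <- x
        tree_log_likelihood(tr, aln, model)
      }
      opt <- optimize(f, interval = c(1e-8, 20), maximum = TRUE, tol = 1e-7)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - start < tol) break
  }
  if (round == max_rounds && cur - start >= tol)
    warning("branch-length optimization did not converge; returning best found")
  attr(tree, "logLik") <- cur
  tree
}

#' Compare substitution models by AIC
#'
#' `AIC = 2k - 2 lnL` with `k` = number of branches plus the model's free
#' parameters (the gamma shape counts as one when `K > 1`; the empirical
#' exchangeabilities and frequencies are fixed constants).
#'
#' @param aln A [protein_alignment()].
#' @param tree Rooted `phylo` with branch lengths.
#' @param candidate_models Named list of [aa_model()] objects.
#' @param optimize If `TRUE`, re-optimize branch lengths under each model
#'   before scoring (slower; default uses the supplied lengths for all
#'   candidates).
#' @return `data.frame` with columns `model`, `lnL`, `k_params`, `AIC`,
#'   `best`, sorted by ascending AIC.
#' @export
aic_compare <- function(aln, tree, candidate_models, optimize = FALSE) {
  if (length(candidate_models) < 1)
    stop_pe("invalid_argument", "need at least one candidate model")
  nm <- names(candidate_models)
  if (is.null(nm))
    nm <- vapply(candidate_models,
                 function(m) sprintf("%s+G%d", m$name, m$K), character(1))
  rows <- lapply(seq_along(candidate_models), function(i) {
    m <- candidate_models[[i]]
    tr <- if (optimize) optimize_branch_lengths(tree, aln, m) else tree
    ll <- if (optimize) attr(tr, "logLik") else tree_log_likelihood(tr, aln, m)
    k <- nrow(tree$edge) + as.integer(m$K > 1)
    data.frame(model = nm[i], lnL = ll, k_params = k,
               AIC = 2 * k - 2 * ll, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$AIC), , drop = FALSE]
  out$best <- seq_len(nrow(out)) == 1
  rownames(out) <- NULL
  out
}
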