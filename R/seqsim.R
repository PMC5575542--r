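# Synthetic data: alignments evolved along a known tree under WAG+G (or
# Poisson) with implanted region x branch substitution-rate multipliers,
# binary presence/absence (indel) columns, and toy dimer coordinate files
# with interface contacts placed by construction.

#' Simulation configuration
#'
#' @param n_leaves Number of leaves for generated trees.
#' @param seq_length Alignment columns.
#' @param model_name `"WAG"` or `"Poisson"`.
#' @param gamma_shape Gamma shape for among-site rate variation.
#' @param n_rate_categories Discrete-gamma categories.
#' @param region_columns Integer columns (1-based) carrying the implanted
#'   rate multiplier.
#' @param multiplier_branches Branch identifiers (each branch is named by
#'   the label of its child node) on which `rate_multiplier` applies to
#'   `region_columns`.
#' @param rate_multiplier Multiplier `m > 0`; `m = 1` is the null.
#' @param indel_column_fraction Fraction of columns carrying a binary
#'   presence/absence character (gain/loss process).
#' @param indel_rate Flip rate of the symmetric two-state gain/loss process,
#'   per unit branch length.
#' @param seed Integer seed.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_leaves = 8, seq_length = 400, model_name = "WAG",
                       gamma_shape = 1, n_rate_categories = 4,
                       region_columns = seq_len(ceiling(seq_length / 5)),
                       multiplier_branches = character(),
                       rate_multiplier = 1,
                       indel_column_fraction = 0.05,
                       indel_rate = 0.2,
                       seed = 1) {
  cfg <- list(n_leaves = as.integer(n_leaves),
              seq_length = as.integer(seq_length),
              model_name = model_name,
              gamma_shape = gamma_shape,
              n_rate_categories = as.integer(n_rate_categories),
              region_columns = as.integer(region_columns),
              multiplier_branches = as.character(multiplier_branches),
              rate_multiplier = rate_multiplier,
              indel_column_fraction = indel_column_fraction,
              indel_rate = indel_rate,
              seed = as.integer(seed))
  if (cfg$n_leaves < 2) stop_pe("config_error", "n_leaves must be >= 2")
  if (cfg$seq_length < 1) stop_pe("config_error", "seq_length must be >= 1")
  if (!cfg$model_name %in% c("WAG", "Poisson"))
    stop_pe("config_error", "unknown model_name '%s'", cfg$model_name)
  if (cfg$gamma_shape <= 0) stop_pe("config_error", "gamma_shape must be > 0")
  if (cfg$rate_multiplier <= 0)
    stop_pe("config_error", "rate_multiplier must be > 0")
  if (length(cfg$region_columns) &&
      (min(cfg$region_columns) < 1 || max(cfg$region_columns) > cfg$seq_length))
    stop_pe("config_error", "region_columns outside [1, seq_length]")
  if (cfg$indel_column_fraction < 0 || cfg$indel_column_fraction > 1)
    stop_pe("config_error", "indel_column_fraction must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Evolve a protein alignment along a tree
#'
#' The root sequence is drawn from the model's stationary frequencies; each
#' site then evolves down each branch with transition probabilities
#' `P(t * r * g)`, where `g` is the site's gamma-category rate (assigned once
#' per site) and `r = m` on multiplier branches for region columns and 1
#' otherwise.  A fraction of columns carries a binary presence/absence
#' character evolved as a symmetric gain/loss process (root present); absent
#' sites appear as gaps.  True states are recorded at every node.
#'
#' @param tree Rooted binary `phylo` with branch lengths (see [gen_tree()]).
#' @param config A [sim_config()].
#' @return Object of class `simulated_dataset`: list with `tree`,
#'   `alignment` ([protein_alignment()] of the leaves), `true_ancestors`
#'   (named list, internal node label -> character vector with gaps),
#'   `true_presence` (named list, node label -> logical), `site_categories`,
#'   `indel_columns` and the `config`.
#' @export
evolve_alignment <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- ensure_node_labels(tree)
  if (any(!is.finite(tree$edge.length)))
    stop_pe("config_error", "tree branch lengths must be finite")
  model <- aa_model(config$model_name, config$gamma_shape,
                    config$n_rate_categories)
  L <- config$seq_length
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  root <- n + 1L
  ctree <- ape::reorder.phylo(tree, "cladewise")
  parent <- ctree$edge[, 1]
  child <- ctree$edge[, 2]
  elen <- ctree$edge.length

  with_seed(config$seed, {
    cats <- sample.int(model$K, L, replace = TRUE)
    states <- matrix(NA_integer_, nn, L)
    states[root, ] <- sample.int(20, L, replace = TRUE, prob = model$pi)

    in_region <- seq_len(L) %in% config$region_columns
    n_indel <- floor(config$indel_column_fraction * L)
    indel_cols <- if (n_indel > 0) sort(sample.int(L, n_indel)) else integer()
    pres <- matrix(TRUE, nn, L)

    for (i in seq_along(parent)) {
      u <- parent[i]
      v <- child[i]
      mult_branch <- node_label(ctree, v) %in% config$multiplier_branches
      # site classes: gamma category x (multiplied or not)
      mfac <- if (mult_branch) ifelse(in_region, config$rate_multiplier, 1)
              else rep(1, L)
      rate <- model$rates[cats] * mfac
      sv <- integer(L)
      for (rv in unique(rate)) {
        idx <- which(rate == rv)
        P <- transition_probs(model, elen[i], rv)
        su <- states[u, idx]
        for (s in unique(su)) {
          j <- idx[su == s]
          sv[j] <- sample.int(20, length(j), replace = TRUE, prob = P[s, ])
        }
      }
      states[v, ] <- sv
      # indel characters: symmetric two-state flip process
      if (length(indel_cols)) {
        pflip <- (1 - exp(-2 * config$indel_rate * elen[i])) / 2
        flip <- runif(length(indel_cols)) < pflip
        pres[v, indel_cols] <- xor(pres[u, indel_cols], flip)
      }
      pres[v, !seq_len(L) %in% indel_cols] <- TRUE
    }

    to_seq <- function(id) {
      s <- AA_CODES[states[id, ]]
      s[!pres[id, ]] <- GAP_CHAR
      s
    }
    leaf_mat <- do.call(rbind, lapply(seq_len(n), to_seq))
    rownames(leaf_mat) <- ctree$tip.label
    anc_ids <- root:nn
    anc <- setNames(lapply(anc_ids, to_seq), node_label(ctree, anc_ids))
    pres_all <- setNames(lapply(seq_len(nn), function(id) pres[id, ]),
                         node_label(ctree, seq_len(nn)))
    structure(list(tree = ctree,
                   alignment = protein_alignment(leaf_mat),
                   true_ancestors = anc,
                   true_presence = pres_all,
                   site_categories = cats,
                   indel_columns = indel_cols,
                   config = config),
              class = "simulated_dataset")
  })
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset: %d leaves x %d columns, m = %g>\n",
              nrow(x$alignment), ncol(x$alignment),
              x$config$rate_multiplier))
  invisible(x)
}
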