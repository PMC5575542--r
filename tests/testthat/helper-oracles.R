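# Independent brute-force oracles used to pin down expected values.
# These deliberately share no code with the package internals they check.

# Exhaustive-likelihood oracle: sum over all internal-node state
# assignments, per site and gamma category.
oracle_site_likelihood <- function(tree, tip_states, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  internals <- (n + 1):(n + tree$Nnode)
  K <- model$K
  total <- 0
  for (k in seq_len(K)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(i)
      transition_probs(model, tree$edge.length[i], model$rates[k]))
    grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(id) {
        if (id <= n) tip_states[id] else grid[g, match(id, internals)]
      }
      pr <- model$pi[grid[g, 1]]  # root is internals[1] (n+1)
      for (i in seq_len(nrow(tree$edge))) {
        su <- assign_state(tree$edge[i, 1])
        sv <- assign_state(tree$edge[i, 2])
        if (is.na(sv)) next        # gap tip: marginalized == factor 1
        pr <- pr * Ps[[i]][su, sv]
      }
      lik <- lik + pr
    }
    total <- total + lik / K
  }
  total
}

oracle_loglik <- function(tree, aln, model) {
  ints <- encode_tips(tree, aln)
  sum(log(vapply(seq_len(ncol(ints)), function(j)
    oracle_site_likelihood(tree, ints[, j], model), numeric(1))))
}

# tip states in tree tip order, integer codes, NA for gap
encode_tips <- function(tree, aln) {
  m <- matrix(match(unclass(aln), AA_CODES), nrow(aln),
              dimnames = dimnames(unclass(aln))[1])
  m[tree$tip.label, , drop = FALSE]
}

# Marginal posterior at one internal node/site by enumeration.
oracle_posterior <- function(tree, tip_states, model, node_id) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  internals <- (n + 1):(n + tree$Nnode)
  K <- model$K
  post <- numeric(20)
  for (k in seq_len(K)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(i)
      transition_probs(model, tree$edge.length[i], model$rates[k]))
    grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(id) {
        if (id <= n) tip_states[id] else grid[g, match(id, internals)]
      }
      pr <- model$pi[grid[g, 1]]
      for (i in seq_len(nrow(tree$edge))) {
        su <- assign_state(tree$edge[i, 1])
        sv <- assign_state(tree$edge[i, 2])
        if (is.na(sv)) next
        pr <- pr * Ps[[i]][su, sv]
      }
      s <- grid[g, match(node_id, internals)]
      post[s] <- post[s] + pr / K
    }
  }
  post / sum(post)
}

# Full hypergeometric enumeration for a 2x2 table with fixed margins.
oracle_fisher <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n2, k)
  pobs <- stats::dhyper(a, m, n2, k)
  if (alternative == "two.sided") {
    sum(probs[probs <= pobs * (1 + 1e-7)])
  } else {
    sum(probs[support >= a])
  }
}

# Minimum-change count for a binary presence pattern by enumeration.
oracle_fitch_changes <- function(tree, pattern) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- ape::Ntip(tree)
  internals <- (n + 1):(n + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)),
                                    length(internals))))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st <- function(id) if (id <= n) pattern[id] else
      grid[g, match(id, internals)]
    ch <- sum(vapply(seq_len(nrow(tree$edge)), function(i)
      st(tree$edge[i, 1]) != st(tree$edge[i, 2]), logical(1)))
    best <- min(best, ch)
  }
  best
}

# Numeric quadrature oracle for discrete-gamma category means.
oracle_gamma_rates <- function(alpha, K) {
  q <- stats::qgamma(seq(0, 1, length.out = K + 1), alpha, alpha)
  vapply(seq_len(K), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                     q[i], q[i + 1], rel.tol = 1e-12)$value * K
  }, numeric(1))
}

# Brute-force rigid-superposition RMSD by optimization over Euler angles.
oracle_min_rmsd <- function(X, Y) {
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  obj <- function(ang) sqrt(mean(rowSums((Xc %*% t(rotmat(ang)) - Yc)^2)))
  best <- Inf
  set.seed(99)
  for (s in 1:40) {
    st <- runif(3, -pi, pi)
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}
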