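# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force enumeration, naive per-pair path sums,
# direct textbook formulas.

# random binary tree with branch lengths and full supports
random_supported_tree <- function(n, supports = 100) {
  tr <- ape::rtree(n)
  tr$node.label <- as.character(rep_len(supports, tr$Nnode))
  tr
}

# patristic distance by explicit root-path edge sums (no cophenetic)
brute_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  path_to_root <- function(v) {
    out <- integer(0)
    while (v != root) {
      out <- c(out, v)
      v <- parent[v]
    }
    out
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    pi_ <- path_to_root(i)
    for (j in (i + 1):ntip) {
      pj <- path_to_root(j)
      sym <- c(setdiff(pi_, pj), setdiff(pj, pi_))
      d[i, j] <- d[j, i] <- sum(elen[sym])
    }
  }
  d
}

# minimum parsimony cost by exhaustive internal-state assignment
brute_parsimony <- function(tree, tip_states, k, cost = 1 - diag(k)) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  grid <- expand.grid(rep(list(0:(k - 1)), length(internal)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    asg <- integer(nn)
    asg[internal] <- as.integer(grid[r, ])
    asg[seq_len(ntip)] <- tip_states
    tot <- sum(cost[cbind(asg[tree$edge[, 1]] + 1L, asg[tree$edge[, 2]] + 1L)])
    best <- min(best, tot)
  }
  best
}

# Mk marginal probabilities by exhaustive summation over internal states
brute_mk_marginals <- function(tree, tip_states, k, q) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  elen <- numeric(nn)
  elen[tree$edge[, 2]] <- tree$edge.length
  pm <- function(t) {
    e <- exp(-k * q * t)
    m <- matrix((1 - e) / k, k, k)
    diag(m) <- (1 + (k - 1) * e) / k
    m
  }
  P <- lapply(seq_len(nn), function(v) pm(elen[v]))
  internal <- (ntip + 1L):nn
  grid <- expand.grid(rep(list(0:(k - 1)), length(internal)))
  marg <- matrix(0, length(internal), k)
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    asg <- integer(nn)
    asg[internal] <- as.integer(grid[r, ])
    asg[seq_len(ntip)] <- tip_states
    lik <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
      lik <- lik * P[[kid]][asg[par] + 1L, asg[kid] + 1L]
    }
    tot <- tot + lik
    for (ii in seq_along(internal)) {
      marg[ii, asg[internal[ii]] + 1L] <- marg[ii, asg[internal[ii]] + 1L] + lik
    }
  }
  list(marginals = marg / tot, lik = tot)
}

# naive per-column parsimony-informative classifier
brute_pi_column <- function(col) {
  col <- col[!(col %in% c("-", "?", "X"))]
  counts <- c(table(col))
  sum(counts >= 2) >= 2
}

# unrooted topological equality
same_topology <- function(a, b) {
  phangorn::RF.dist(ape::unroot(a), ape::unroot(b)) == 0
}

# tip-label sets of all internal nodes (root included)
node_clades_for_test <- function(tree) {
  lapply(ape::prop.part(tree), function(i) tree$tip.label[i])
}
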