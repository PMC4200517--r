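#' Mk-model marginal ancestral states for one character
#'
#' Fits the symmetric k-state Mk model (equal rates, uniform stationary
#' frequencies) to a single discrete character by maximum likelihood -- one
#' rate parameter, optimised in 1-D -- and computes the marginal posterior
#' probability of every state at every internal node via the standard
#' two-pass (down/up) pruning algorithm, equivalent to re-rooting at each
#' node. The closed-form transition probability is
#' `P(i -> j, t) = 1/k - exp(-k q t)/k` for `i != j`, with `q` the
#' off-diagonal rate.
#'
#' @param tree Rooted `phylo` with branch lengths; >= 3 tips.
#' @param states Named character (or integer) vector of single tip states
#'   (`"0"`, `"1"`, ...); taxa with missing or polymorphic cells must be
#'   pruned beforehand.
#' @param k Number of states; defaults to `max(states) + 1`.
#' @param rate Fixed off-diagonal rate `q`; estimated by ML when `NULL`.
#' @return An `mk_ancestral` object: list with `rate`, `loglik`,
#'   `invariant` flag, and `marginals` (tibble `node`, `state`, `prob`).
#'   [tidy()] returns the marginals; [glance()] a one-row summary with the
#'   root's best state.
#' @export
mk_ancestral <- function(tree, states, k = NULL, rate = NULL) {
  if (is.null(names(states))) abort("`states` must be named by taxon.")
  if (!setequal(names(states), tree$tip.label)) {
    abort("`states` must cover exactly the tree's tips.")
  }
  s <- as.integer(as.character(states[tree$tip.label]))
  if (anyNA(s)) abort("States must be single non-negative integers.")
  if (is.null(k)) k <- max(s) + 1L
  if (length(tree$tip.label) < 3) abort("Need at least 3 taxa.")
  if (is.null(tree$edge.length)) abort("Tree must have branch lengths.")
  invariant <- length(unique(s)) < 2

  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  elen <- numeric(nn)
  elen[post$edge[, 2]] <- post$edge.length

  pmat <- function(t, q) {
    e <- exp(-k * q * t)
    m <- base::matrix((1 - e) / k, k, k)
    diag(m) <- (1 + (k - 1) * e) / k
    m
  }

  down_pass <- function(q) {
    L <- base::matrix(0, nn, k)
    L[cbind(seq_len(ntip), s + 1L)] <- 1
    D <- base::matrix(NA_real_, nn, k)  # child's contribution seen from its parent
    init <- rep(TRUE, nn)
    for (e in seq_len(nrow(post$edge))) {
      par <- post$edge[e, 1]; kid <- post$edge[e, 2]
      D[kid, ] <- pmat(elen[kid], q) %*% L[kid, ]
      if (init[par]) { L[par, ] <- 1; init[par] <- FALSE }
      L[par, ] <- L[par, ] * D[kid, ]
    }
    root <- ntip + 1L
    list(L = L, D = D, loglik = log(sum(L[root, ] / k)))
  }

  loglik_fn <- function(q) down_pass(q)$loglik

  if (is.null(rate)) {
    # the log-likelihood flattens for large rates; bracket the optimum on a
    # log-spaced grid before the local search, or golden section can stall
    # on the plateau
    h <- max(ape::node.depth.edgelength(tree))
    grid <- exp(seq(log(1e-6 / h), log(100 / h), length.out = 30))
    ll <- vapply(grid, loglik_fn, numeric(1))
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    rate <- if (lo == hi) lo else {
      optimize(loglik_fn, interval = c(lo, hi), maximum = TRUE)$maximum
    }
  }
  dp <- down_pass(rate)
  L <- dp$L; D <- dp$D
  root <- ntip + 1L

  # up pass: U[v, ] = P(t_v) %*% (U[parent, ] * prod of siblings' D)
  U <- base::matrix(0, nn, k)
  U[root, ] <- 1 / k
  cw <- ape::reorder.phylo(tree, "cladewise")
  elen_cw <- numeric(nn); elen_cw[cw$edge[, 2]] <- cw$edge.length
  for (e in seq_len(nrow(cw$edge))) {
    par <- cw$edge[e, 1]; v <- cw$edge[e, 2]
    if (v <= ntip) next
    sibs <- cw$edge[cw$edge[, 1] == par & cw$edge[, 2] != v, 2]
    M <- U[par, ]
    for (w in sibs) M <- M * D[w, ]
    U[v, ] <- as.numeric(pmat(elen_cw[v], rate) %*% M)  # symmetric P
    sc <- max(U[v, ])
    if (sc > 0) U[v, ] <- U[v, ] / sc
  }

  marg <- base::matrix(NA_real_, tree$Nnode, k)
  for (v in (ntip + 1L):nn) {
    m <- L[v, ] * U[v, ]
    marg[v - ntip, ] <- m / sum(m)
  }
  marginals <- tibble(
    node = rep((ntip + 1L):nn, each = k),
    state = rep(0:(k - 1L), tree$Nnode),
    prob = as.numeric(t(marg))
  )
  structure(
    list(tree = tree, k = k, rate = rate, loglik = dp$loglik,
         invariant = invariant, marginals = marginals),
    class = "mk_ancestral"
  )
}

#' @export
print.mk_ancestral <- function(x, ...) {
  cat(sprintf("<mk_ancestral> k = %d, rate = %.4g, logLik = %.3f%s\n",
              x$k, x$rate, x$loglik,
              if (x$invariant) " (invariant character)" else ""))
  invisible(x)
}

#' @rdname mk_ancestral
#' @param x An `mk_ancestral` object.
#' @param ... Unused.
#' @method tidy mk_ancestral
#' @export
tidy.mk_ancestral <- function(x, ...) x$marginals

#' @rdname mk_ancestral
#' @method glance mk_ancestral
#' @export
glance.mk_ancestral <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  root <- best_state_at(x, ntip + 1L)
  tibble(k = x$k, rate = x$rate, loglik = x$loglik,
         invariant = x$invariant,
         root_state = root$state, root_margin = root$margin)
}

#' Best state and log-likelihood margin at a node
#'
#' @param x An `mk_ancestral` object.
#' @param node Internal node number.
#' @return A list: `state` (integer), `prob`, `margin` (log probability
#'   ratio of best over runner-up state; `Inf` for a certain node).
#' @export
best_state_at <- function(x, node) {
  m <- x$marginals |> filter(.data$node == !!node)
  if (nrow(m) == 0) abort(paste0("Node not in reconstruction: ", node))
  ord <- order(m$prob, decreasing = TRUE)
  p1 <- m$prob[ord[1]]; p2 <- m$prob[ord[2]]
  list(state = m$state[ord[1]], prob = p1,
       margin = if (p2 <= 0) Inf else log(p1) - log(p2))
}

#' Detect character novelties on focal branches
#'
#' For each character, the Mk marginal reconstruction is computed on the
#' tree pruned (for that character) of taxa with missing or polymorphic
#' cells, as the likelihood model requires fixed tip states. A character is
#' a novelty on the branch subtending a focal clade when the best states at
#' the clade's crown node and at its parent node differ and both
#' reconstructions are decisive (log-likelihood margin >= `margin`, default
#' 2 -- the conventional significance rule for ancestral states).
#'
#' @param matrix A `morph_matrix`.
#' @param tree Rooted `phylo` with branch lengths covering the matrix taxa.
#' @param focal_clades Named list of taxon sets; each clade's crown node is
#'   the MRCA of its members present in the (per-character pruned) tree.
#' @param margin Decisiveness threshold on the log-likelihood margin.
#' @param rate Optional fixed Mk rate (estimated per character when
#'   `NULL`).
#' @return A tibble: `character`, `clade`, `parent_state`, `node_state`,
#'   `parent_margin`, `node_margin`, `novelty`.
#' @export
detect_novelties <- function(matrix, tree, focal_clades, margin = 2,
                             rate = NULL) {
  if (!inherits(matrix, "morph_matrix")) matrix <- morph_matrix(matrix)
  if (is.null(names(focal_clades))) abort("`focal_clades` must be named.")
  unknown <- setdiff(unlist(focal_clades), tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("Focal taxa not in tree: ", paste(unknown, collapse = ", ")))
  }
  n_states <- attr(matrix, "n_states")

  rows <- list()
  for (j in seq_len(ncol(matrix))) {
    cells <- matrix[, j]
    keep <- names(cells)[cells != "?" & nchar(cells) == 1]
    keep <- intersect(keep, tree$tip.label)
    if (length(keep) < 3) next
    sub <- ape::keep.tip(tree, keep)
    st <- setNames(cells[keep], keep)
    if (length(unique(st)) < 2) next  # invariant: flat reconstruction
    anc <- mk_ancestral(sub, st, k = n_states[j], rate = rate)
    for (nm in names(focal_clades)) {
      members <- intersect(focal_clades[[nm]], sub$tip.label)
      if (length(members) < 2) next
      node <- ape::getMRCA(sub, members)
      root <- length(sub$tip.label) + 1L
      if (node == root) next  # no subtending branch
      parent <- sub$edge[sub$edge[, 2] == node, 1]
      b_node <- best_state_at(anc, node)
      b_par <- best_state_at(anc, parent)
      rows[[length(rows) + 1L]] <- tibble(
        character = colnames(matrix)[j], clade = nm,
        parent_state = b_par$state, node_state = b_node$state,
        parent_margin = b_par$margin, node_margin = b_node$margin,
        novelty = b_node$state != b_par$state &&
          b_node$margin >= margin && b_par$margin >= margin
      )
    }
  }
  bind_rows(rows)
}
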