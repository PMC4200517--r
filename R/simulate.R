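#' Synthetic phylogenomic study generator
#'
#' `sim_config()` collects every knob of the synthetic-data module in one
#' place; `sim_bundle()` runs the whole generator. The defaults mirror a
#' transcriptome-scale nuclear marker study: 59 genes for a 26-taxon ingroup
#' plus one outgroup, ~400 aligned amino acids per gene (the per-gene share
#' of a ~25 kaa supermatrix), Yule species tree of height 0.5
#' substitutions/site, and gamma rate variation across sites.
#'
#' Reproducibility: one global integer `seed`; gene `i` uses the derived
#' substream seed `seed + 1009 * i`, so adding genes never reshuffles the
#' genes already generated.
#'
#' @param seed Integer seed for all randomness.
#' @param n_taxa Ingroup taxon count.
#' @param n_genes Number of genes.
#' @param birth Yule speciation rate (relative; tree is rescaled to `height`).
#' @param height Root-to-tip height of the species tree, expected
#'   substitutions/site.
#' @param outgroup Outgroup tip label attached below the ingroup root (length
#'   `height`); `NULL` for none.
#' @param mode Gene-tree discordance mode: `"nni"` (each gene tree is the
#'   species tree after `k` random rooted NNI moves) or `"coalescent"`
#'   (multispecies coalescent with population parameter `theta`).
#' @param k NNI moves per gene (`mode = "nni"`).
#' @param theta Coalescent population-size parameter in branch-length units
#'   (`mode = "coalescent"`); discordance grows with `theta`.
#' @param columns Alignment columns per gene.
#' @param gamma_shape Shape of the gamma distribution of site rates
#'   (discretised into `n_rate_cat` categories).
#' @param n_rate_cat Number of discrete gamma categories.
#' @param long_branch Named numeric vector: terminal-branch multipliers
#'   (>= 1) for taxa to be injected as long branches in every gene.
#' @param saturated Named numeric vector: whole-tree rate multipliers (>= 1)
#'   for genes to be simulated as saturated, e.g. `c(g07 = 10)`.
#' @return `sim_config()`: a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_taxa = 26, n_genes = 59, birth = 1,
                       height = 0.5, outgroup = "OUT",
                       mode = c("nni", "coalescent"), k = 1, theta = 0.05,
                       columns = 400, gamma_shape = 1, n_rate_cat = 4,
                       long_branch = NULL, saturated = NULL) {
  mode <- match.arg(mode)
  if (!is.null(long_branch) && any(long_branch < 1)) {
    abort("Long-branch multipliers must be >= 1.")
  }
  if (!is.null(saturated) && any(saturated < 1)) {
    abort("Saturation rate multipliers must be >= 1.")
  }
  structure(as.list(environment()), class = "sim_config")
}

gene_seed <- function(seed, i) as.integer((seed + 1009 * i) %% .Machine$integer.max)

#' Simulate an ultrametric Yule species tree
#'
#' @inheritParams sim_config
#' @return A rooted ultrametric `phylo`, tips `t01..tNN` (plus `outgroup`),
#'   scaled so the ingroup root-to-tip height equals `height`.
#' @examples
#' tr <- simulate_species_tree(6, seed = 1)
#' @export
simulate_species_tree <- function(n_taxa, birth = 1, height = 0.5,
                                  outgroup = NULL, seed = NULL) {
  if (n_taxa < 3) abort("Need n_taxa >= 3.")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth, death = 0)
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * height / depth
  if (!is.null(outgroup)) {
    # graft the outgroup below the ingroup root, keeping the tree ultrametric
    stem <- height / 2
    ing <- sub(";$", "", ape::write.tree(tr))
    tr <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f);",
                                        outgroup, height + stem, ing, stem))
  }
  tr
}

#' One random rooted NNI move
#'
#' Picks a random internal edge (parent u, internal child v) and swaps a
#' random child of v with v's sibling. Keeps the tree rooted and binary;
#' branch lengths travel with their child nodes.
#' @keywords internal
rooted_nni <- function(tree) {
  ntip <- length(tree$tip.label)
  cand <- which(tree$edge[, 2] > ntip)  # internal, non-root child
  if (length(cand) == 0L) return(tree)
  e <- cand[sample.int(length(cand), 1L)]
  u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
  sibs <- tree$edge[tree$edge[, 1] == u & tree$edge[, 2] != v, 2]
  w <- sibs[sample.int(length(sibs), 1L)]
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  cc <- kids[sample.int(length(kids), 1L)]
  iw <- which(tree$edge[, 1] == u & tree$edge[, 2] == w)
  ic <- which(tree$edge[, 1] == v & tree$edge[, 2] == cc)
  tree$edge[iw, 1] <- v
  tree$edge[ic, 1] <- u
  attr(tree, "order") <- NULL  # edge order is stale after surgery
  ape::reorder.phylo(tree, "cladewise")
}

#' Simulate gene trees with controlled discordance
#'
#' @param species_tree Rooted `phylo` with branch lengths.
#' @inheritParams sim_config
#' @param n_genes Number of gene trees.
#' @param seed Integer seed (per-gene substreams derived from it).
#' @return Named list (`g01`, `g02`, ...) of rooted `phylo` objects; all
#'   internal nodes carry support 100 (these are noiseless "true" trees).
#' @export
simulate_gene_trees <- function(species_tree, n_genes = 59,
                                mode = c("nni", "coalescent"),
                                k = 1, theta = 0.05, seed = 1) {
  mode <- match.arg(mode)
  out <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    set.seed(gene_seed(seed, i))
    gt <- if (mode == "nni") {
      g <- species_tree
      if (k > 0) for (m in seq_len(k)) g <- rooted_nni(g)
      g
    } else {
      msc_gene_tree(species_tree, theta)
    }
    gt$node.label <- rep("100", gt$Nnode)
    out[[i]] <- gt
  }
  names(out) <- sprintf("g%02d", seq_len(n_genes))
  out
}

#' Multispecies-coalescent gene tree (one sample per species)
#'
#' Standard bottom-up simulation: within each species-tree branch, the
#' lineages present coalesce at rate choose(j, 2)/theta until the branch's
#' top is reached; remaining lineages are passed up, with the root branch
#' extended to infinity. As theta -> 0 coalescences become instantaneous and
#' the gene tree converges to the species topology.
#' @keywords internal
msc_gene_tree <- function(species_tree, theta) {
  st <- species_tree
  ntip <- length(st$tip.label)
  depth <- ape::node.depth.edgelength(st)
  h <- max(depth) - depth  # node heights above the tips

  # a lineage is a list(newick fragment without trailing ';', height of its root)
  coalesce_in <- function(lins, h_bottom, h_top) {
    t <- h_bottom
    while (length(lins) > 1L) {
      j <- length(lins)
      dt <- if (theta <= 0) 0 else rexp(1, rate = choose(j, 2) / theta)
      if (t + dt > h_top) break
      t <- t + dt
      pick <- sample.int(j, 2L)
      a <- lins[[pick[1]]]; b <- lins[[pick[2]]]
      merged <- list(
        frag = sprintf("(%s:%.10f,%s:%.10f)", a$frag, t - a$h, b$frag, t - b$h),
        h = t
      )
      lins <- c(lins[-pick], list(merged))
    }
    lins
  }

  walk <- function(node) {
    if (node <= ntip) {
      list(list(frag = st$tip.label[node], h = h[node]))
    } else {
      kids <- st$edge[st$edge[, 1] == node, 2]
      unlist(lapply(kids, function(kid) {
        lins <- walk(kid)
        coalesce_in(lins, h[kid], h[node])
      }), recursive = FALSE)
    }
  }

  root <- ntip + 1L
  lins <- walk(root)
  lins <- coalesce_in(lins, h[root], Inf)
  ape::read.tree(text = paste0(lins[[1]]$frag, ";"))
}

#' Simulate an amino-acid alignment along a tree
#'
#' Site-independent Markov substitution under a uniform-exchangeability
#' 20-state model (all exchangeabilities and base frequencies equal), with
#' gamma-distributed rate variation across sites discretised into
#' `n_rate_cat` equal-probability categories.
#'
#' @param tree Rooted `phylo` with branch lengths (substitutions/site).
#' @inheritParams sim_config
#' @param rate Overall rate multiplier applied to all branches.
#' @param seed Integer seed.
#' @return An alignment character matrix (see [as_msa()]).
#' @export
simulate_alignment <- function(tree, columns = 400, gamma_shape = 1,
                               n_rate_cat = 4, rate = 1, seed = NULL) {
  if (is.null(tree$edge.length)) abort("Tree must have branch lengths.")
  if (!is.null(seed)) set.seed(seed)
  rates <- if (is.finite(gamma_shape)) {
    phangorn::discrete.gamma(gamma_shape, n_rate_cat)
  } else {
    1
  }
  nblock <- rep(columns %/% length(rates), length(rates))
  extra <- columns %% length(rates)
  if (extra > 0) nblock[seq_len(extra)] <- nblock[seq_len(extra)] + 1L
  blocks <- lapply(seq_along(rates), function(b) {
    if (nblock[b] == 0L) return(NULL)
    s <- phangorn::simSeq(tree, l = nblock[b], type = "AA",
                          rate = rates[b] * rate)
    as.character(s)
  })
  m <- do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
  as_msa(m)
}

#' Inject a long terminal branch
#'
#' Multiplies the terminal branch of `taxon` by `multiplier` (>= 1), the
#' generator's model of a fast-evolving or artefact-bearing sequence.
#'
#' @param tree A `phylo` with branch lengths.
#' @param taxon Tip label.
#' @param multiplier Branch multiplier (>= 1).
#' @return The modified tree.
#' @export
stretch_terminal_branch <- function(tree, taxon, multiplier) {
  if (multiplier < 1) abort("Multiplier must be >= 1.")
  i <- match(taxon, tree$tip.label)
  if (is.na(i)) abort(paste0("Taxon not in tree: ", taxon))
  e <- which(tree$edge[, 2] == i)
  tree$edge.length[e] <- tree$edge.length[e] * multiplier
  tree
}

#' Simulate Mk-evolved morphological characters with an event log
#'
#' Each character evolves independently along the tree under the symmetric
#' k-state Mk model (total leaving rate `rate` per branch-length unit, jumps
#' uniform over the other states), simulated as an explicit jump chain so
#' the realised number of state changes is recorded. Parsimony steps on the
#' generating tree can never exceed that realised count.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param n_chars Number of characters.
#' @param n_states States per character (>= 2).
#' @param rate Total substitution rate per branch-length unit.
#' @param seed Integer seed.
#' @return A `morph_matrix` (taxa x characters, states `"0"..`) whose
#'   `"true_changes"` attribute logs the realised change count per character.
#' @export
simulate_morphology <- function(tree, n_chars = 110, n_states = 3,
                                rate = 1, seed = NULL) {
  if (n_states < 2) abort("Need n_states >= 2.")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edge <- tree$edge
  elen <- tree$edge.length %||% rep(0, nrow(edge))

  mat <- matrix(NA_character_, ntip, n_chars,
                dimnames = list(tree$tip.label, sprintf("c%03d", seq_len(n_chars))))
  changes <- integer(n_chars)
  for (ch in seq_len(n_chars)) {
    state <- integer(ntip + tree$Nnode)
    state[root] <- sample.int(n_states, 1L) - 1L
    nch <- 0L
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1]; kid <- edge[e, 2]
      s <- state[par]
      njump <- rpois(1, rate * elen[e])
      if (njump > 0) {
        for (j in seq_len(njump)) {
          others <- setdiff(0:(n_states - 1L), s)
          s <- others[sample.int(length(others), 1L)]
        }
        nch <- nch + njump
      }
      state[kid] <- s
    }
    changes[ch] <- nch
    mat[, ch] <- as.character(state[seq_len(ntip)])
  }
  morph_matrix(mat, ordered = rep(FALSE, n_chars), true_changes = changes)
}

#' @rdname sim_config
#' @param config A `sim_config`.
#' @return `sim_bundle()`: a list of class `sim_bundle` with the species
#'   tree, a `genes` tibble (`gene`, true `tree`, perturbed `sim_tree`,
#'   `alignment`), the ground-truth `truth` list (long-branch taxa,
#'   saturated genes, species-tree clades) and the `config`.
#' @export
sim_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  st <- simulate_species_tree(config$n_taxa, config$birth, config$height,
                              config$outgroup, seed = config$seed)
  gts <- simulate_gene_trees(st, config$n_genes, config$mode,
                             k = config$k, theta = config$theta,
                             seed = config$seed)
  genes <- tibble(gene = names(gts), tree = unname(gts))
  genes$sim_tree <- map(seq_len(nrow(genes)), function(i) {
    tr <- genes$tree[[i]]
    for (tx in names(config$long_branch)) {
      if (tx %in% tr$tip.label) {
        tr <- stretch_terminal_branch(tr, tx, config$long_branch[[tx]])
      }
    }
    mult <- unname(config$saturated[genes$gene[i]])
    if (length(mult) == 0 || is.na(mult)) mult <- 1
    tr$edge.length <- tr$edge.length * mult
    tr
  })
  genes$alignment <- map(seq_len(nrow(genes)), function(i) {
    simulate_alignment(genes$sim_tree[[i]], columns = config$columns,
                       gamma_shape = config$gamma_shape,
                       n_rate_cat = config$n_rate_cat,
                       seed = gene_seed(config$seed, i) + 1L)
  })
  structure(
    list(
      config = config,
      species_tree = st,
      genes = genes,
      truth = list(
        long_branch_taxa = names(config$long_branch),
        saturated_genes = names(config$saturated),
        clades = node_clades(st)
      )
    ),
    class = "sim_bundle"
  )
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d taxa, %d genes (%s mode), seed %d\n",
              length(x$species_tree$tip.label), nrow(x$genes),
              x$config$mode, x$config$seed))
  invisible(x)
}
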