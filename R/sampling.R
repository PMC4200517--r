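#' Design a random gene-subsampling experiment
#'
#' Draws `replicates` random gene subsets (without replacement within a
#' subset) for every gene count on the grid. The default grid, 2 to 58 in
#' steps of 2 with 20 replicates, yields 580 subsets. Sampling is
#' deterministic under `seed`.
#'
#' @param genes Character vector of gene ids.
#' @param counts Gene-count grid (positive, each <= `length(genes)`).
#' @param replicates Replicates per count.
#' @param seed Integer seed.
#' @return A tibble: `n_genes`, `replicate`, `genes` (list column of gene
#'   ids).
#' @examples
#' nrow(draw_subsets(sprintf("g%02d", 1:59), seed = 1))
#' @export
draw_subsets <- function(genes, counts = seq(2, 58, by = 2),
                         replicates = 20, seed = 1) {
  if (any(counts < 1) || any(counts > length(genes))) {
    abort(sprintf("Counts must lie in [1, %d].", length(genes)))
  }
  if (replicates < 1) abort("Need at least one replicate.")
  set.seed(seed)
  design <- expand_grid(n_genes = counts, replicate = seq_len(replicates))
  design$genes <- map(design$n_genes, function(k) sample(genes, k))
  design
}

#' Infer a tree from an alignment (internal NJ backend, bootstrap supports)
#'
#' The internal backend computes uncorrected p-distances, applies the
#' Poisson correction for amino acids, `d = -ln(1 - p)`, and runs
#' neighbour-joining; supports are the percentage of column-resampled
#' bootstrap replicates whose NJ tree contains each bipartition. An
#' arbitrary external backend (e.g. a maximum-likelihood program) can be
#' supplied as a function taking `(msa, seed)` and returning a `phylo`.
#'
#' @param msa An alignment (see [as_msa()]), >= 4 taxa.
#' @param backend `"nj"` or a function `(msa, seed) -> phylo`.
#' @param bootstrap_reps Bootstrap replicates (0 for none).
#' @param seed Integer seed for the bootstrap resampling.
#' @return A `phylo`; with bootstrapping, internal `node.label` holds
#'   percent support.
#' @export
infer_tree <- function(msa, backend = "nj", bootstrap_reps = 100, seed = 1) {
  if (is.function(backend)) return(backend(msa, seed))
  if (!identical(backend, "nj")) abort("Unknown backend.")
  msa <- as_msa(msa)
  if (nrow(msa) < 3) abort("Need at least 3 taxa.")

  tr <- nj_poisson(msa)
  if (bootstrap_reps > 0) {
    set.seed(seed)
    boots <- vector("list", bootstrap_reps)
    for (b in seq_len(bootstrap_reps)) {
      cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
      boots[[b]] <- tryCatch(nj_poisson(msa[, cols, drop = FALSE]),
                             error = function(e) NULL)
    }
    boots <- boots[!vapply(boots, is.null, logical(1))]
    counts <- ape::prop.clades(tr, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tr$node.label <- as.character(round(100 * counts / length(boots)))
  }
  tr
}

nj_poisson <- function(msa) {
  p <- p_distances(msa)
  if (anyNA(p)) abort("Some pairs share no comparable columns.")
  if (any(p >= 1)) {
    abort("p-distance >= 1: Poisson correction undefined (saturation?).")
  }
  d <- -log(1 - p)
  tr <- ape::nj(as.dist(d))
  # NJ can emit slightly negative branches; clamp to zero (standard practice)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Clade-recovery curves over a subsampling experiment
#'
#' For each target clade and gene count, the proportion of replicate trees
#' that contain the clade as an (unrooted) bipartition -- support values are
#' ignored for presence. Two minimal gene numbers are summarised per clade:
#' `first_full`, the smallest grid count reaching proportion 1.0, and
#' `sustained_full`, the smallest count from which every larger grid count
#' also stays at 1.0 (robust to single-point flukes).
#'
#' @param trees A tibble with columns `n_genes`, `replicate` and `tree`
#'   (list of `phylo`), e.g. a [draw_subsets()] design with inferred trees.
#' @param clades Named list of taxon sets.
#' @return A `recovery_curve`: tibble `clade`, `n_genes`, `n_trees`,
#'   `n_recovered`, `prop`. [glance()] returns the per-clade minimal counts.
#' @export
recovery_curve <- function(trees, clades) {
  stopifnot(all(c("n_genes", "tree") %in% names(trees)))
  if (is.null(names(clades))) abort("`clades` must be a named list.")
  rows <- imap(clades, function(taxa, nm) {
    hit <- map_lgl(trees$tree, clade_in_tree, taxa = taxa)
    tibble(clade = nm, n_genes = trees$n_genes, hit = hit)
  })
  curve <- bind_rows(rows) |>
    group_by(.data$clade, .data$n_genes) |>
    summarise(n_trees = n(), n_recovered = sum(.data$hit),
              prop = mean(.data$hit), .groups = "drop") |>
    arrange(.data$clade, .data$n_genes)
  structure(curve, class = c("recovery_curve", class(curve)))
}

#' @rdname recovery_curve
#' @param x A `recovery_curve`.
#' @param ... Unused.
#' @method glance recovery_curve
#' @export
glance.recovery_curve <- function(x, ...) {
  x |>
    group_by(.data$clade) |>
    arrange(.data$n_genes, .by_group = TRUE) |>
    summarise(
      first_full = first_at_one(.data$n_genes, .data$prop, sustained = FALSE),
      sustained_full = first_at_one(.data$n_genes, .data$prop, sustained = TRUE),
      .groups = "drop"
    )
}

first_at_one <- function(n_genes, prop, sustained) {
  full <- prop >= 1
  if (!any(full)) return(NA_integer_)
  if (!sustained) return(as.integer(n_genes[which(full)[1]]))
  # smallest count such that this and all larger counts are at 1.0
  rev_ok <- rev(cumprod(rev(full))) == 1
  if (!any(rev_ok)) return(NA_integer_)
  as.integer(n_genes[which(rev_ok)[1]])
}

#' Nested supermatrices from ranked genes
#'
#' Builds one supermatrix per step point, each concatenating the top-k
#' ranked genes in rank order; successive matrices are nested (each is a
#' column-prefix of the next).
#'
#' @param alignments Named list of gene alignments.
#' @param ranked_genes Character vector of gene ids in rank order (best
#'   first).
#' @param steps Ascending step points (each <= number of ranked genes).
#' @param taxa Optional master taxon list (see [concatenate()]).
#' @return Named list of `supermatrix` objects (`"top16"`, ...).
#' @export
ranked_accumulation <- function(alignments, ranked_genes,
                                steps = c(16, 25, 33, 41, 46, 50, 55),
                                taxa = NULL) {
  if (is.unsorted(steps, strictly = TRUE)) abort("`steps` must be ascending.")
  if (max(steps) > length(ranked_genes)) {
    abort("Step point exceeds the number of ranked genes.")
  }
  missing <- setdiff(ranked_genes, names(alignments))
  if (length(missing) > 0) {
    abort(paste0("No alignment for gene(s): ", paste(missing, collapse = ", ")))
  }
  out <- lapply(steps, function(k) {
    concatenate(alignments[ranked_genes[seq_len(k)]], taxa = taxa)
  })
  names(out) <- paste0("top", steps)
  out
}
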