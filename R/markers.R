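#' Filter ortholog groups by taxon coverage and relative length
#'
#' An ortholog group (OG) is kept when the species that retain a sequence
#' make up at least `coverage_min` of the species panel, where a sequence is
#' retained only if its coding length is at least `length_min` times the
#' reference species' homologue length. The defaults (80%/80%) are the
#' usual missing-data guard for transcriptome-derived marker sets.
#'
#' @param og_table Tibble/data frame with columns `og`, `species`, `length`
#'   (residues; one row per OG x species with a recovered sequence).
#' @param ref_lengths Tibble with columns `og`, `ref_length`. Every OG in
#'   `og_table` must have a reference length.
#' @param species Character vector: the full species panel the coverage
#'   denominator refers to. Defaults to the distinct species in `og_table`.
#' @param coverage_min Minimum fraction of the panel with a retained
#'   sequence.
#' @param length_min Minimum length as a fraction of the reference length.
#' @return A tibble, one row per OG: `og`, `n_retained`, `coverage`, `kept`.
#'   Row order of the input never affects the result.
#' @examples
#' tab <- tibble::tibble(og = "OG1", species = c("a", "b"), length = c(90, 100))
#' refs <- tibble::tibble(og = "OG1", ref_length = 100)
#' filter_ogs(tab, refs, species = c("a", "b"))
#' @export
filter_ogs <- function(og_table, ref_lengths, species = NULL,
                       coverage_min = 0.8, length_min = 0.8) {
  og_table <- as_tibble(og_table)
  ref_lengths <- as_tibble(ref_lengths)
  stopifnot(all(c("og", "species", "length") %in% names(og_table)),
            all(c("og", "ref_length") %in% names(ref_lengths)))
  if (any(og_table$length <= 0, na.rm = TRUE)) {
    abort("Sequence lengths must be positive.")
  }
  missing_ref <- setdiff(unique(og_table$og), ref_lengths$og)
  if (length(missing_ref) > 0) {
    abort(paste0("No reference length for OG(s): ",
                 paste(sort(missing_ref), collapse = ", ")))
  }
  if (is.null(species)) species <- unique(og_table$species)
  n_sp <- length(species)

  og_table |>
    filter(.data$species %in% !!species) |>
    left_join(ref_lengths, by = "og") |>
    mutate(retained = .data$length >= length_min * .data$ref_length) |>
    group_by(.data$og) |>
    summarise(n_retained = sum(.data$retained, na.rm = TRUE), .groups = "drop") |>
    mutate(coverage = .data$n_retained / n_sp,
           kept = .data$coverage >= coverage_min) |>
    arrange(.data$og)
}

#' Vet a single-gene tree for hidden paralogy
#'
#' After condensing the gene tree at `support_cutoff`, the gene is excluded
#' if any supported clade mixes members of two or more reference monophyletic
#' groups while containing all sampled members of none of them -- the
#' signature of hidden paralogy (different species contributing different
#' post-duplication copies). A clade that simply unites one complete group
#' with parts of another (or contains everything) is a legitimate nesting and
#' does not offend.
#'
#' @param gene_tree A `phylo` with support values.
#' @param groups Named list of disjoint taxon sets, the reference
#'   monophyletic groups (taxa not listed are unclassified and ignored).
#' @param support_cutoff Condensation cutoff in percent (default 50).
#' @return A one-row tibble: `verdict` (`"selected"`/`"excluded"`) and
#'   `offending_clade` (list column; tip labels of the first, smallest
#'   offending clade, or `NULL`).
#' @export
vet_gene_tree <- function(gene_tree, groups, support_cutoff = 50) {
  if (anyDuplicated(unlist(groups))) abort("Reference groups must be disjoint.")
  ct <- condense_tree(gene_tree, support_cutoff)
  tips <- ct$tip.label
  sampled <- lapply(groups, intersect, tips)
  if (sum(lengths(sampled)) == 0) {
    abort("No leaves from any reference group in the gene tree.")
  }
  clades <- node_clades(ct)
  clades <- clades[order(lengths(clades))]
  offending <- NULL
  for (cl in clades) {
    inside <- vapply(sampled, function(g) length(intersect(g, cl)) > 0, logical(1))
    if (sum(inside) < 2) next
    complete <- vapply(sampled[inside], function(g) all(g %in% cl), logical(1))
    if (!any(complete)) {
      offending <- cl
      break
    }
  }
  tibble(
    verdict = if (is.null(offending)) "selected" else "excluded",
    offending_clade = list(offending)
  )
}

#' Score a gene tree's per-taxon congruence with a species tree
#'
#' On the support-condensed gene tree restricted to the taxa shared with the
#' species tree, each taxon's "position" is its smallest non-trivial
#' containing clade (the leaf set under its parent node). The taxon scores
#' `+1` when that set is compatible with the species tree (for a fully
#' resolved species tree: it is one of its clades, restricted to shared
#' taxa), `-1` when it conflicts (overlaps a species-tree clade without
#' nesting either way), and `0` when the taxon hangs from the root polytomy,
#' i.e. has no supported local position. The gene's total score is the sum.
#'
#' @param gene_tree,species_tree Rooted `phylo` objects; only shared taxa
#'   are scored (at least 4 required).
#' @param support_cutoff Condensation cutoff in percent (default 50).
#' @return A `congruence_report`: tibble with columns `taxon`, `score` and
#'   `clade` (list column), plus attributes `total` and `n_shared`.
#'   [glance()] gives a one-row summary.
#' @examples
#' sp <- read_newick("(((A,B),(C,D)),(E,F));")
#' gt <- read_newick("(((A,B)100,(C,D)100)100,(E,F)100);")
#' glance(score_congruence(gt, sp))
#' @export
score_congruence <- function(gene_tree, species_tree, support_cutoff = 50) {
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4) {
    abort("Fewer than 4 shared taxa; congruence scoring is uninformative.")
  }
  gt <- condense_tree(gene_tree, support_cutoff)
  gt <- ape::keep.tip(gt, shared)
  st <- ape::keep.tip(species_tree, shared)

  sp_clades <- lapply(node_clades(st), sort)
  ntip <- length(gt$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + gt$Nnode)
  parent[gt$edge[, 2]] <- gt$edge[, 1]
  gt_clades <- node_clades(gt)

  res <- map(seq_len(ntip), function(i) {
    p <- parent[i]
    if (p == root) return(list(score = 0L, clade = NULL))
    cl <- sort(gt_clades[[as.character(p)]])
    if (any(vapply(sp_clades, identical, logical(1), y = cl))) {
      return(list(score = 1L, clade = cl))
    }
    compatible <- all(vapply(sp_clades, function(s) {
      ov <- length(intersect(s, cl))
      ov == 0 || ov == length(s) || ov == length(cl)
    }, logical(1)))
    list(score = if (compatible) 1L else -1L, clade = cl)
  })

  out <- tibble(
    taxon = gt$tip.label,
    score = vapply(res, `[[`, integer(1), "score"),
    clade = map(res, "clade")
  )
  structure(out, class = c("congruence_report", class(out)),
            total = sum(out$score), n_shared = length(shared))
}

#' @rdname score_congruence
#' @param x A `congruence_report`.
#' @param ... Unused.
#' @method glance congruence_report
#' @export
glance.congruence_report <- function(x, ...) {
  tibble(total = attr(x, "total"),
         n_shared = attr(x, "n_shared"),
         n_congruent = sum(x$score == 1L),
         n_conflicting = sum(x$score == -1L),
         n_uncertain = sum(x$score == 0L))
}

#' Score and rank a set of gene trees against a species tree
#'
#' `score_genes()` applies [score_congruence()] to every gene tree;
#' `rank_genes()` orders genes by descending total score, breaking ties by
#' gene id (lexicographic, stable).
#'
#' @param gene_trees Named list of rooted `phylo` objects.
#' @param species_tree Rooted reference `phylo`.
#' @param support_cutoff Condensation cutoff in percent.
#' @return A tibble `gene`, `total` (and after ranking, `rank` 1-based).
#' @export
score_genes <- function(gene_trees, species_tree, support_cutoff = 50) {
  if (is.null(names(gene_trees))) abort("`gene_trees` must be named.")
  tibble(
    gene = names(gene_trees),
    total = map_int(gene_trees, function(gt) {
      as.integer(attr(score_congruence(gt, species_tree, support_cutoff), "total"))
    })
  )
}

#' @rdname score_genes
#' @param reports A tibble with columns `gene` and `total` (e.g. from
#'   `score_genes()`).
#' @export
rank_genes <- function(reports) {
  reports <- as_tibble(reports)
  stopifnot(all(c("gene", "total") %in% names(reports)))
  if (nrow(reports) < 1) abort("Need at least one report.")
  if (anyDuplicated(reports$gene)) {
    abort(paste0("Duplicate gene ids: ",
                 paste(unique(reports$gene[duplicated(reports$gene)]),
                       collapse = ", ")))
  }
  reports |>
    arrange(desc(.data$total), .data$gene) |>
    mutate(rank = row_number())
}

#' Keep only the shortest-branch copy of each duplicated species
#'
#' For species represented by more than one leaf (recent in-paralogs), only
#' the leaf with the smallest terminal branch length is retained; the others
#' are pruned and unary nodes cleaned up. Exact ties keep the copy that
#' appears first in the tree's tip order (documented tie-break).
#'
#' @param gene_tree A `phylo` with branch lengths.
#' @param species_of_leaf Named character vector mapping every leaf label to
#'   its species.
#' @return The pruned `phylo`.
#' @export
prune_shortest_paralog <- function(gene_tree, species_of_leaf) {
  tips <- gene_tree$tip.label
  unknown <- setdiff(tips, names(species_of_leaf))
  if (length(unknown) > 0) {
    abort(paste0("Leaves without species mapping: ",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(gene_tree$edge.length)) {
    abort("Tree must have branch lengths to compare paralog copies.")
  }
  term <- setNames(gene_tree$edge.length[match(seq_along(tips),
                                               gene_tree$edge[, 2])], tips)
  sp <- species_of_leaf[tips]
  drop <- character(0)
  for (s in unique(sp)) {
    copies <- tips[sp == s]
    if (length(copies) > 1) {
      keep <- copies[which.min(term[copies])]
      drop <- c(drop, setdiff(copies, keep))
    }
  }
  if (length(drop) == 0) return(gene_tree)
  ape::drop.tip(gene_tree, drop)
}
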