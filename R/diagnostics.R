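#' Long-branch (LB) scores of the taxa in a tree
#'
#' The LB score of taxon i is its percent deviation from the tree-wide
#' average patristic distance:
#' `LB_i = (mean_j PD(i, j) / mean_pairwise_PD - 1) * 100` (j over the other
#' taxa, the denominator over all unordered pairs). Scores sum to zero on
#' every tree and are invariant to uniform branch-length scaling; large
#' positive values flag taxa sitting on long branches.
#'
#' @param tree A `phylo` with branch lengths, >= 3 taxa.
#' @return A tibble `taxon`, `lb` (percent deviation).
#' @examples
#' lb_scores(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))
#' @export
lb_scores <- function(tree) {
  if (length(tree$tip.label) < 3) abort("Need at least 3 taxa.")
  pd <- patristic_distances(tree)
  n <- nrow(pd)
  overall <- sum(pd) / (n * (n - 1))  # mean over unordered pairs
  if (overall <= 0) abort("All patristic distances are zero; LB undefined.")
  mean_i <- rowSums(pd) / (n - 1)
  tibble(taxon = rownames(pd), lb = unname(mean_i / overall - 1) * 100)
}

#' Per-gene summaries of LB scores
#'
#' For each gene tree: the mean of the upper quartile of its taxon LB scores
#' (values at or above the 75th percentile, linear-interpolation convention)
#' and the sample standard deviation of all its LB scores. Genes whose trees
#' contain long-branch sequences stand out on either summary.
#'
#' @param gene_trees Named list of `phylo` objects with branch lengths.
#' @return A tibble `gene`, `lb_upper_mean`, `lb_sd`.
#' @export
gene_lb_summary <- function(gene_trees) {
  if (is.null(names(gene_trees))) abort("`gene_trees` must be named.")
  rows <- imap(gene_trees, function(tr, g) {
    lb <- lb_scores(tr)$lb
    q3 <- quantile(lb, 0.75, names = FALSE)
    tibble(gene = g, lb_upper_mean = mean(lb[lb >= q3]), lb_sd = sd(lb))
  })
  bind_rows(rows)
}

#' Gene-by-taxon LB score matrix with flags
#'
#' Long format suitable for heatmaps: one row per (gene, taxon) with the
#' taxon-specific LB score in that gene's tree; cells above `threshold`
#' (default 150, the conventional long-branch alarm level) are flagged.
#' Taxa absent from a gene are absent from its rows.
#'
#' @param gene_trees Named list of `phylo` objects.
#' @param threshold Flagging threshold on the LB score.
#' @return A tibble `gene`, `taxon`, `lb`, `flagged`.
#' @export
taxon_gene_matrix <- function(gene_trees, threshold = 150) {
  if (is.null(names(gene_trees))) abort("`gene_trees` must be named.")
  rows <- imap(gene_trees, function(tr, g) {
    lb_scores(tr) |> mutate(gene = g, .before = 1)
  })
  bind_rows(rows) |>
    mutate(flagged = .data$lb > threshold) |>
    arrange(.data$gene, .data$taxon)
}

#' Substitution-saturation regression for one gene
#'
#' Ordinary least squares of the uncorrected p-distance (response) on the
#' patristic distance (predictor) over all taxon pairs shared between the
#' gene tree and its alignment. With no saturation p grows ~linearly with
#' PD (slope near the per-site substitution scale, R^2 near 1); repeated
#' substitutions flatten the relationship, so smaller slopes and smaller
#' R^2 values mean more saturation.
#'
#' @param tree Gene tree (`phylo` with branch lengths).
#' @param msa The gene's alignment.
#' @return A one-row `saturation_fit` tibble: `slope`, `intercept`, `r2`,
#'   `n_pairs`; the pairwise data are kept in the `"pairs"` attribute for
#'   plotting.
#' @export
saturation_fit <- function(tree, msa) {
  msa <- as_msa(msa)
  shared <- intersect(tree$tip.label, rownames(msa))
  if (length(shared) < 3) abort("Need at least 3 shared taxa.")
  pd <- patristic_distances(ape::keep.tip(tree, shared))[shared, shared]
  p <- p_distances(msa[shared, , drop = FALSE])[shared, shared]
  iu <- upper.tri(pd)
  pairs <- tibble(pd = pd[iu], p = p[iu]) |> filter(!is.na(.data$p))
  if (nrow(pairs) < 3) abort("Fewer than 3 usable taxon pairs.")
  if (sd(pairs$pd) == 0) abort("Zero variance in patristic distances.")
  fit <- lm(p ~ pd, data = pairs)
  ss_tot <- sum((pairs$p - mean(pairs$p))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  out <- tibble(slope = unname(coef(fit)[2]),
                intercept = unname(coef(fit)[1]),
                r2 = r2, n_pairs = nrow(pairs))
  structure(out, class = c("saturation_fit", class(out)), pairs = pairs)
}

#' @rdname saturation_fit
#' @param gene_trees Named list of gene trees.
#' @param alignments Named list of matching alignments (same names).
#' @return `saturation_table()`: a tibble with one row per gene.
#' @export
saturation_table <- function(gene_trees, alignments) {
  genes <- names(gene_trees)
  if (!all(genes %in% names(alignments))) {
    abort("Every gene tree needs a matching alignment.")
  }
  bind_rows(lapply(genes, function(g) {
    as_tibble(saturation_fit(gene_trees[[g]], alignments[[g]])) |>
      mutate(gene = g, .before = 1)
  }))
}

#' Flag outlier genes in a per-gene statistic
#'
#' Two reproducible replacements for eyeballing density-plot "shoulders":
#' the Tukey fence rule (beyond `Q3 + 1.5 IQR` for `direction = "high"`,
#' below `Q1 - 1.5 IQR` for `"low"`) and a kernel-density rule that flags
#' values beyond the local density minimum separating a minor outlying mode
#' from the main mode (no flag when the density is unimodal). Both are
#' reported; the fence rule is the deterministic default for downstream
#' pruning.
#'
#' @param values Tibble with columns `gene` and `value` (or a named numeric
#'   vector).
#' @param direction `"high"` (e.g. LB summaries) or `"low"` (e.g. slope,
#'   R^2).
#' @return A tibble `gene`, `value`, `flag_iqr`, `flag_kde`.
#' @export
flag_outlier_genes <- function(values, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (is.numeric(values)) {
    values <- tibble(gene = names(values) %||% as.character(seq_along(values)),
                     value = unname(values))
  }
  values <- as_tibble(values)
  stopifnot(all(c("gene", "value") %in% names(values)))
  x <- values$value
  if (length(x) < 8) abort("Need at least 8 genes to define a distribution.")

  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  flag_iqr <- if (direction == "high") x > q[2] + 1.5 * iqr else x < q[1] - 1.5 * iqr

  flag_kde <- rep(FALSE, length(x))
  if (sd(x) > 0) {
    d <- density(x)
    y <- d$y
    mins <- which(diff(sign(diff(y))) == 2) + 1L  # local minima
    mode_x <- d$x[which.max(y)]
    cut <- if (direction == "high") {
      cand <- d$x[mins]; cand <- cand[cand > mode_x]
      if (length(cand) > 0) min(cand) else NA_real_  # first dip right of mode
    } else {
      cand <- d$x[mins]; cand <- cand[cand < mode_x]
      if (length(cand) > 0) max(cand) else NA_real_  # first dip left of mode
    }
    if (!is.na(cut)) {
      flag_kde <- if (direction == "high") x > cut else x < cut
    }
  }
  values |> mutate(flag_iqr = flag_iqr, flag_kde = flag_kde)
}
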