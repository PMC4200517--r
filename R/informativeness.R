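#' Parsimony-informative site statistics
#'
#' A column is parsimony informative (PI) when at least two distinct
#' residue states each occur in at least two sequences; gaps and missing
#' symbols never count as states. The fraction uses all columns as the
#' denominator.
#'
#' @param msa An alignment (>= 4 sequences; PI is undefined below that).
#' @return A one-row tibble: `n_columns`, `pi_sites`, `pi_percent`.
#' @examples
#' m <- as_msa(c(a = "AT", b = "AT", c = "TA", d = "TA"))
#' pi_stats(m)
#' @export
pi_stats <- function(msa) {
  msa <- as_msa(msa)
  if (nrow(msa) < 4) abort("PI requires at least 4 sequences.")
  pi <- apply(msa, 2, function(col) {
    tab <- table(col[!(col %in% msa_missing_symbols)])
    sum(tab >= 2) >= 2
  })
  tibble(n_columns = ncol(msa),
         pi_sites = sum(pi),
         pi_percent = 100 * sum(pi) / ncol(msa))
}

#' @rdname pi_stats
#' @param alignments Named list of alignments.
#' @return `pi_table()`: one row per gene (`gene`, `n_columns`, `pi_sites`,
#'   `pi_percent`).
#' @export
pi_table <- function(alignments) {
  if (is.null(names(alignments))) abort("`alignments` must be named.")
  bind_rows(imap(alignments, function(al, g) {
    pi_stats(al) |> mutate(gene = g, .before = 1)
  }))
}

#' Partition genes into rate classes by PI percentage
#'
#' For each cutoff c, genes split into a slower set (`<set>_less_<c>`,
#' PI < c) and a faster set (`<set>_greater_<c>`, PI >= c; a gene exactly at
#' the cutoff goes to the greater side). Optional PI bands
#' `<set>_<a>_PI_<b>` collect genes with a <= PI < b. Each named gene set is
#' emitted as a concatenated [supermatrix][concatenate()]; empty sides are
#' dropped with a warning.
#'
#' @param alignments Named list of gene alignments.
#' @param pi A [pi_table()] result (columns `gene`, `pi_percent`); computed
#'   from `alignments` when `NULL`.
#' @param cutoffs PI percentage cutoffs, e.g. `c(30, 40, 50)`.
#' @param bands Optional list of 2-vectors `c(a, b)` for band matrices.
#' @param set_name Prefix naming the gene set (e.g. `"IR"`, `"SC"`).
#' @param taxa Optional master taxon list.
#' @return Named list of `supermatrix` objects.
#' @export
partition_by_pi <- function(alignments, pi = NULL, cutoffs = c(30, 40, 50),
                            bands = NULL, set_name = "IR", taxa = NULL) {
  if (is.null(pi)) pi <- pi_table(alignments)
  pi <- as_tibble(pi)
  stopifnot(all(c("gene", "pi_percent") %in% names(pi)))
  pi <- pi |> filter(.data$gene %in% names(alignments))

  sets <- list()
  for (c0 in cutoffs) {
    sets[[sprintf("%s_less_%g", set_name, c0)]] <-
      pi$gene[pi$pi_percent < c0]
    sets[[sprintf("%s_greater_%g", set_name, c0)]] <-
      pi$gene[pi$pi_percent >= c0]
  }
  for (b in bands) {
    sets[[sprintf("%s_%g_PI_%g", set_name, b[1], b[2])]] <-
      pi$gene[pi$pi_percent >= b[1] & pi$pi_percent < b[2]]
  }

  out <- list()
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (length(g) == 0) {
      warn(sprintf("Gene set '%s' is empty; matrix suppressed.", nm))
      next
    }
    out[[nm]] <- concatenate(alignments[g], taxa = taxa)
  }
  out
}
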