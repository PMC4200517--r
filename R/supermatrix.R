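#' Concatenate gene alignments into a supermatrix
#'
#' Genes are appended in the order given; a taxon absent from a gene is
#' padded with gaps across that gene's columns. Partition bookkeeping uses
#' 1-based inclusive column intervals. Per-taxon gene coverage is the
#' fraction of genes in which the taxon has a sequence.
#'
#' @param alignments Named list of alignments (see [as_msa()]); names are the
#'   gene ids.
#' @param taxa Master taxon list. Defaults to the union of all gene taxa, in
#'   order of first appearance. Every gene's taxa must be a subset.
#' @return A `supermatrix` object: a list with elements `msa` (character
#'   matrix), `partitions` (tibble `gene`, `start`, `end`) and `coverage`
#'   (tibble `taxon`, `n_genes`, `coverage`).
#' @examples
#' g1 <- as_msa(c(A = "MKL", B = "MKI"))
#' g2 <- as_msa(c(A = "ML", C = "MI"))
#' sm <- concatenate(list(g1 = g1, g2 = g2))
#' glance(sm)
#' @export
concatenate <- function(alignments, taxa = NULL) {
  if (is.null(names(alignments)) || any(names(alignments) == "")) {
    abort("`alignments` must be a named list (gene ids).")
  }
  if (anyDuplicated(names(alignments))) {
    abort(paste0("Duplicate gene ids: ",
                 paste(unique(names(alignments)[duplicated(names(alignments))]),
                       collapse = ", ")))
  }
  alignments <- lapply(alignments, as_msa)
  all_taxa <- unique(unlist(lapply(alignments, rownames)))
  if (is.null(taxa)) taxa <- all_taxa
  extra <- setdiff(all_taxa, taxa)
  if (length(extra) > 0) {
    abort(paste0("Gene taxa not in master list: ", paste(extra, collapse = ", ")))
  }

  widths <- vapply(alignments, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  total <- sum(widths)

  big <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  present <- matrix(FALSE, length(taxa), length(alignments),
                    dimnames = list(taxa, names(alignments)))
  for (k in seq_along(alignments)) {
    al <- alignments[[k]]
    big[rownames(al), starts[k]:ends[k]] <- al
    present[rownames(al), k] <- TRUE
  }

  structure(
    list(
      msa = big,
      partitions = tibble(gene = names(alignments),
                          start = unname(starts), end = unname(ends)),
      coverage = tibble(taxon = taxa,
                        n_genes = unname(rowSums(present)),
                        coverage = unname(rowSums(present)) / length(alignments))
    ),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d columns, %d partitions\n",
              nrow(x$msa), ncol(x$msa), nrow(x$partitions)))
  cat(sprintf("  mean gene coverage %.1f%%\n", 100 * mean(x$coverage$coverage)))
  invisible(x)
}

#' @rdname concatenate
#' @param x A `supermatrix`.
#' @param ... Unused.
#' @method tidy supermatrix
#' @export
tidy.supermatrix <- function(x, ...) x$partitions

#' @rdname concatenate
#' @method glance supermatrix
#' @export
glance.supermatrix <- function(x, ...) {
  tibble(
    n_taxa = nrow(x$msa),
    n_genes = nrow(x$partitions),
    n_columns = ncol(x$msa),
    coverage_mean = mean(x$coverage$coverage),
    coverage_min = min(x$coverage$coverage),
    coverage_max = max(x$coverage$coverage)
  )
}

#' Export a supermatrix for external ML backends
#'
#' `write_partitions()` writes RAxML-style `GENE, start-end` lines;
#' `write_phylip_msa()` writes relaxed (long-name) sequential PHYLIP.
#'
#' @param sm A `supermatrix`.
#' @param path Output file path.
#' @param type Partition data type tag, e.g. `"JTT"` for amino-acid models.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(sm, path, type = "JTT") {
  stopifnot(inherits(sm, "supermatrix"))
  lines <- sprintf("%s, %s = %d-%d", type, sm$partitions$gene,
                   sm$partitions$start, sm$partitions$end)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_partitions
#' @param msa An alignment matrix or `supermatrix`.
#' @export
write_phylip_msa <- function(msa, path) {
  if (inherits(msa, "supermatrix")) msa <- msa$msa
  msa <- as_msa(msa)
  lines <- c(sprintf("%d %d", nrow(msa), ncol(msa)),
             sprintf("%s  %s", rownames(msa),
                     apply(msa, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}
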