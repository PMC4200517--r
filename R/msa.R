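#' Alignment containers and FASTA input/output
#'
#' Alignments are plain character matrices: one row per taxon (rownames are
#' the taxon labels), one column per aligned site, upper-case residue symbols
#' with `-` for gaps and `?`/`X` for missing data. `as_msa()` validates and
#' normalises any rectangular character input into this form.
#'
#' @param x A character matrix, or a named list/vector of equal-length
#'   unaligned-to-aligned sequence strings.
#' @return A validated character matrix with unique rownames.
#' @export
as_msa <- function(x) {
  if (is.list(x) || (is.character(x) && !is.matrix(x))) {
    nm <- names(x)
    if (is.null(nm) || any(nm == "")) {
      abort("Sequences must be named by taxon.")
    }
    seqs <- setNames(
      vapply(x, function(s) paste(toupper(s), collapse = ""), character(1),
             USE.NAMES = FALSE),
      nm
    )
    n <- unique(nchar(seqs))
    if (length(n) != 1L) {
      abort(sprintf("Sequences have unequal lengths: %s.",
                    paste(sort(unique(nchar(seqs))), collapse = ", ")))
    }
    x <- do.call(rbind, strsplit(seqs, ""))
    rownames(x) <- names(seqs)
  }
  if (!is.matrix(x) || !is.character(x)) {
    abort("An alignment must be a character matrix.")
  }
  if (is.null(rownames(x))) abort("Alignment rows must be named by taxon.")
  if (anyDuplicated(rownames(x))) abort("Duplicate taxon labels in alignment.")
  x[] <- toupper(x)
  x
}

#' @rdname as_msa
#' @param path Path to a FASTA file.
#' @export
read_fasta_msa <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  as_msa(lapply(recs, identity))
}

#' @rdname as_msa
#' @param msa An alignment matrix.
#' @export
write_fasta_msa <- function(msa, path) {
  msa <- as_msa(msa)
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(msa)), function(i) msa[i, ]),
    names = rownames(msa), file.out = path, nbchar = 60
  )
  invisible(path)
}

msa_missing_symbols <- c("-", "?", "X")

#' Uncorrected pairwise p-distances
#'
#' The p-distance between two aligned sequences is the proportion of
#' differing sites among sites comparable in both, without any correction
#' for multiple substitutions. Columns where either sequence has a gap (`-`)
#' or missing symbol (`?`, `X`) are excluded pair by pair (pairwise
#' deletion), which keeps patchy alignments comparable per pair.
#'
#' @param msa An alignment (see [as_msa()]).
#' @return A symmetric numeric matrix of proportions in \[0, 1\]. Pairs with
#'   zero comparable columns are `NA` and reported in the
#'   `"undefined_pairs"` attribute.
#' @examples
#' m <- as_msa(c(a = "AAAA", b = "AAAT", c = "AA-A"))
#' p_distances(m)
#' @export
p_distances <- function(msa) {
  msa <- as_msa(msa)
  n <- nrow(msa)
  if (n < 2L) abort("Need at least two sequences.")
  ok <- !matrix(msa %in% msa_missing_symbols, nrow = n)
  taxa <- rownames(msa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  undef <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      m <- sum(comp)
      if (m == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        undef[[length(undef) + 1L]] <- c(taxa[i], taxa[j])
      } else {
        p <- sum(msa[i, comp] != msa[j, comp]) / m
        d[i, j] <- d[j, i] <- p
      }
    }
  }
  if (length(undef) > 0) {
    warn(sprintf("%d pair(s) share no comparable columns; set to NA.",
                 length(undef)))
    attr(d, "undefined_pairs") <- undef
  }
  d
}
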