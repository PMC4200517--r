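#' Multistate morphological character matrices
#'
#' A `morph_matrix` is a taxa x characters character matrix whose cells are
#' state strings: `"0"` (fixed), `"02"` (polymorphic: states 0 and 2),
#' `"?"` (missing, equivalent to the full state set). Per-character
#' metadata: `ordered` (logical; ordered characters pay |i - j| steps per
#' change, unordered pay 1) and `n_states`.
#'
#' @param x Character matrix with taxon rownames.
#' @param ordered Logical vector (recycled) of per-character ordered flags.
#' @param true_changes Optional integer vector (simulator event log).
#' @return A `morph_matrix` object.
#' @export
morph_matrix <- function(x, ordered = FALSE, true_changes = NULL) {
  if (!is.matrix(x) || !is.character(x)) abort("Need a character matrix.")
  if (is.null(rownames(x))) abort("Rows must be named by taxon.")
  if (is.null(colnames(x))) colnames(x) <- sprintf("c%03d", seq_len(ncol(x)))
  ordered <- rep_len(ordered, ncol(x))
  x[is.na(x) | x %in% c("-", "")] <- "?"
  n_states <- apply(x, 2, function(col) {
    st <- unlist(strsplit(col[col != "?"], ""))
    if (length(st) == 0) 0L else max(as.integer(st)) + 1L
  })
  structure(x, class = c("morph_matrix", "matrix"),
            ordered = ordered, n_states = n_states,
            true_changes = true_changes)
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat(sprintf("<morph_matrix> %d taxa x %d characters (%d ordered)\n",
              nrow(x), ncol(x), sum(attr(x, "ordered"))))
  invisible(x)
}

#' Read a morphological matrix from NEXUS or TSV
#'
#' Parses the `MATRIX` command of a NEXUS `DATA`/`CHARACTERS` block:
#' `SYMBOLS`, `MISSING` and `GAP` from the `FORMAT` command, polymorphic
#' cells written `(01)` or `{01}`. Characters listed in an
#' `ASSUMPTIONS`/`TYPESET` line (`ord: 4 17;`) are marked ordered; with no
#' such block all characters are unordered. The TSV fallback expects taxa
#' in the first column and one character per remaining column, `?` for
#' missing and multi-digit strings for polymorphism.
#'
#' @param path File path.
#' @return A `morph_matrix`.
#' @export
read_morph_nexus <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip NEXUS comments
  missing_sym <- "?"
  gap_sym <- "-"
  fmt <- regmatches(txt, regexpr("(?i)FORMAT[^;]*;", txt, perl = TRUE))
  if (length(fmt) == 1) {
    m <- regmatches(fmt, regexpr("(?i)MISSING\\s*=\\s*\\S", fmt, perl = TRUE))
    if (length(m) == 1) missing_sym <- substr(m, nchar(m), nchar(m))
    g <- regmatches(fmt, regexpr("(?i)GAP\\s*=\\s*\\S", fmt, perl = TRUE))
    if (length(g) == 1) gap_sym <- substr(g, nchar(g), nchar(g))
  }

  mat_m <- regmatches(txt, regexpr("(?i)\\bMATRIX\\b\\s*\\n(.|\n)*?;", txt,
                                   perl = TRUE))
  if (length(mat_m) == 0) abort("No MATRIX command found in NEXUS file.")
  body <- sub("(?i)^MATRIX", "", mat_m, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  lines <- trimws(strsplit(body, "\n")[[1]])
  lines <- lines[lines != "" & !grepl("^\\[", lines)]

  taxa <- character(0)
  rows <- list()
  for (ln in lines) {
    # taxon label (possibly quoted) followed by the character string
    m <- regmatches(ln, regexec("^('[^']+'|\"[^\"]+\"|\\S+)\\s+(.*)$", ln))[[1]]
    if (length(m) != 3) abort(paste0("Cannot parse MATRIX row: ", ln))
    tx <- gsub("^['\"]|['\"]$", "", m[2])
    states <- gsub("\\s", "", m[3])
    cells <- parse_state_string(states, missing_sym, gap_sym)
    taxa <- c(taxa, tx)
    rows[[length(rows) + 1L]] <- cells
  }
  if (length(unique(lengths(rows))) != 1) {
    abort("MATRIX rows have differing character counts.")
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- taxa

  ordered <- rep(FALSE, ncol(mat))
  ts <- regmatches(txt, regexpr("(?i)TYPESET[^;]*;", txt, perl = TRUE))
  if (length(ts) == 1) {
    om <- regmatches(ts, regexpr("(?i)ord\\s*:\\s*[0-9 .-]+", ts, perl = TRUE))
    if (length(om) == 1) {
      spec <- trimws(sub("(?i)ord\\s*:\\s*", "", om, perl = TRUE))
      idx <- unlist(lapply(strsplit(spec, "\\s+")[[1]], function(tok) {
        if (grepl("-", tok)) {
          ab <- as.integer(strsplit(tok, "-")[[1]])
          seq(ab[1], ab[2])
        } else {
          as.integer(tok)
        }
      }))
      ordered[idx] <- TRUE
    }
  }
  morph_matrix(mat, ordered = ordered)
}

parse_state_string <- function(s, missing_sym, gap_sym) {
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("(", "{")) {
      close <- if (ch == "(") ")" else "}"
      j <- i + 1L
      while (j <= n && substr(s, j, j) != close) j <- j + 1L
      if (j > n) abort("Unclosed polymorphism in MATRIX.")
      poly <- gsub("[ ,]", "", substr(s, i + 1L, j - 1L))
      out <- c(out, paste(sort(strsplit(poly, "")[[1]]), collapse = ""))
      i <- j + 1L
    } else {
      if (ch == missing_sym || ch == gap_sym) ch <- "?"
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' @rdname read_morph_nexus
#' @export
read_morph_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                   colClasses = "character", check.names = FALSE)
  morph_matrix(as.matrix(df))
}

#' Enumerate all backbone topologies for a set of lineages
#'
#' Generates every rooted binary arrangement of `k` lineage placeholders --
#' there are (2k-3)!! of them (3 for k=3, 15 for k=4, 105 for k=5) -- then
#' grafts each lineage's fixed within-group subtree in place of its
#' placeholder and roots the whole tree on the outgroup. Only the spine
#' joining the lineages varies.
#'
#' @param groups Named list: lineage name -> character vector of its taxa
#'   (length-1 groups stay single tips). Sets must be disjoint.
#' @param subtrees Optional named list of `phylo` objects fixing the
#'   within-group topology for multi-taxon groups; a group without one gets
#'   an arbitrary pectinate arrangement of its taxa.
#' @param outgroup Character vector of outgroup taxa attached as the root's
#'   other child (`NULL` for none).
#' @return A list of `phylo` objects (topologies only, no branch lengths).
#' @examples
#' length(enumerate_backbones(list(A = "a", B = "b", C = "c", D = "d", E = "e")))
#' @export
enumerate_backbones <- function(groups, subtrees = NULL, outgroup = NULL) {
  k <- length(groups)
  if (k < 2) abort("Need at least 2 lineages.")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be named.")
  }
  if (anyDuplicated(unlist(c(groups, list(outgroup))))) {
    abort("Lineage (and outgroup) taxon sets must be disjoint.")
  }

  sub_newick <- function(taxa, nm) {
    if (!is.null(subtrees[[nm]])) {
      tr <- subtrees[[nm]]
      if (!setequal(tr$tip.label, taxa)) {
        abort(paste0("Subtree for group '", nm, "' has different taxa."))
      }
      return(sub(";$", "", ape::write.tree(tr)))
    }
    if (length(taxa) == 1) return(taxa)
    # pectinate fallback
    nwk <- taxa[1]
    for (t in taxa[-1]) nwk <- sprintf("(%s,%s)", nwk, t)
    nwk
  }
  frags <- imap(groups, function(taxa, nm) sub_newick(taxa, nm))

  spines <- if (k == 2) {
    list(ape::read.tree(text = sprintf("(%s,%s);", names(groups)[1],
                                       names(groups)[2])))
  } else {
    phangorn::allTrees(k, rooted = TRUE, tip.label = names(groups))
  }

  lapply(spines, function(sp) {
    nwk <- sub(";$", "", ape::write.tree(sp))
    for (nm in names(groups)) {
      nwk <- gsub(paste0("(?<![A-Za-z0-9_])", nm, "(?![A-Za-z0-9_])"),
                  frags[[nm]], nwk, perl = TRUE)
    }
    if (!is.null(outgroup)) {
      og <- if (length(outgroup) == 1) outgroup else {
        o <- outgroup[1]
        for (t in outgroup[-1]) o <- sprintf("(%s,%s)", o, t)
        o
      }
      nwk <- sprintf("(%s,%s)", og, nwk)
    }
    ape::read.tree(text = paste0(nwk, ";"))
  })
}

#' Parsimony step counts for a morphological matrix on a tree
#'
#' Minimum number of state changes per character and in total. Unordered
#' characters use the Fitch state-set pass (generalised to polytomies via
#' the Sankoff recursion, which it equals under uniform costs); ordered
#' characters use Sankoff dynamic programming with linear step-ladder costs
#' `|i - j|`. Missing cells contribute the full state set, polymorphic
#' cells their listed set (no within-taxon step). Characters with fewer
#' than two observed states contribute zero and are flagged.
#'
#' @param matrix A `morph_matrix` (or plain character matrix).
#' @param tree A `phylo`; its leaves must all be scored in the matrix, and
#'   matrix taxa absent from the tree are ignored.
#' @return A list with `total` (integer) and `per_character` (tibble:
#'   `character`, `steps`, `ordered`, `informative`).
#' @examples
#' m <- morph_matrix(matrix(c("0", "0", "1", "1"), 4, 1,
#'                          dimnames = list(c("A", "B", "C", "D"), "c1")))
#' parsimony_steps(m, read_newick("((A,B),(C,D));"))$total
#' @export
parsimony_steps <- function(matrix, tree) {
  if (!inherits(matrix, "morph_matrix")) matrix <- morph_matrix(matrix)
  missing_taxa <- setdiff(tree$tip.label, rownames(matrix))
  if (length(missing_taxa) > 0) {
    abort(paste0("Tree taxa not in matrix: ",
                 paste(missing_taxa, collapse = ", ")))
  }
  ordered <- attr(matrix, "ordered")
  n_states <- attr(matrix, "n_states")

  per <- map(seq_len(ncol(matrix)), function(j) {
    cells <- matrix[tree$tip.label, j]
    obs <- unlist(strsplit(cells[cells != "?"], ""))
    if (length(unique(obs)) < 2) {
      return(list(steps = 0L, informative = FALSE))
    }
    k <- n_states[j]
    cost <- if (ordered[j]) {
      abs(outer(0:(k - 1), 0:(k - 1), "-"))
    } else {
      1 - diag(k)
    }
    list(steps = sankoff_steps(tree, cells, k, cost), informative = TRUE)
  })

  per_character <- tibble(
    character = colnames(matrix),
    steps = vapply(per, function(x) as.integer(x$steps), integer(1)),
    ordered = ordered,
    informative = vapply(per, `[[`, logical(1), "informative")
  )
  list(total = sum(per_character$steps), per_character = per_character)
}

#' Sankoff parsimony for a single character
#'
#' Postorder dynamic programme: the cost of assigning state s to a node is
#' the sum over children of the minimum of (child cost + transition cost).
#' Tips allow their listed states at cost 0 (`"?"` allows all states).
#' Handles multifurcations and arbitrary cost matrices.
#'
#' @param tree A `phylo`.
#' @param cells Named (or tree-tip-ordered) character vector of state
#'   strings for the tips.
#' @param k Number of states.
#' @param cost k x k transition cost matrix.
#' @return Minimum total cost (numeric).
#' @export
sankoff_steps <- function(tree, cells, k, cost = 1 - diag(k)) {
  ntip <- length(tree$tip.label)
  if (!is.null(names(cells))) cells <- cells[tree$tip.label]
  tree <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  C <- base::matrix(Inf, nn, k)
  for (i in seq_len(ntip)) {
    allowed <- if (cells[i] == "?") seq_len(k) else {
      as.integer(strsplit(cells[i], "")[[1]]) + 1L
    }
    C[i, allowed] <- 0
  }
  init <- rep(TRUE, nn); init[seq_len(ntip)] <- FALSE
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
    if (init[par]) { C[par, ] <- 0; init[par] <- FALSE }
    kidmin <- apply(cost + base::matrix(C[kid, ], k, k, byrow = TRUE), 1, min)
    C[par, ] <- C[par, ] + kidmin
  }
  min(C[ntip + 1L, ])
}

#' Fitch parsimony for a single unordered character on a binary tree
#'
#' Classic state-set pass: a node takes the intersection of its children's
#' sets when non-empty, otherwise their union at the price of one step.
#'
#' @inheritParams sankoff_steps
#' @return Number of steps (integer).
#' @export
fitch_steps <- function(tree, cells, k) {
  ntip <- length(tree$tip.label)
  if (!is.null(names(cells))) cells <- cells[tree$tip.label]
  if (any(tabulate(tree$edge[, 1]) > 2)) {
    abort("Fitch pass requires a binary tree; use sankoff_steps().")
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    sets[[i]] <- if (cells[i] == "?") 0:(k - 1) else {
      as.integer(strsplit(cells[i], "")[[1]])
    }
  }
  steps <- 0L
  # postorder guarantees a child's set is complete when its edge is visited;
  # fold children into the parent incrementally (binary: one fold per node)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
    if (is.null(sets[[par]])) {
      sets[[par]] <- sets[[kid]]
    } else {
      s <- intersect(sets[[par]], sets[[kid]])
      if (length(s) == 0) {
        s <- union(sets[[par]], sets[[kid]])
        steps <- steps + 1L
      }
      sets[[par]] <- s
    }
  }
  steps
}

#' Step counts for every backbone topology
#'
#' Convenience wrapper: applies [parsimony_steps()] to each enumerated
#' backbone and returns an ascending step report.
#'
#' @param matrix A `morph_matrix`.
#' @param backbones List of `phylo` objects (e.g. [enumerate_backbones()]);
#'   names are kept if present.
#' @return A tibble `topology`, `newick`, `steps`, sorted ascending.
#' @export
backbone_steps <- function(matrix, backbones) {
  nm <- names(backbones) %||% sprintf("T%03d", seq_along(backbones))
  tibble(
    topology = nm,
    newick = vapply(backbones, function(tr) ape::write.tree(tr), character(1)),
    steps = vapply(backbones, function(tr) parsimony_steps(matrix, tr)$total,
                   numeric(1))
  ) |> arrange(.data$steps)
}
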