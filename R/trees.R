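#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that enforce
#' the package's conventions: internal-node labels carry bootstrap-style
#' support values in percent (the usual RAxML dialect), branch lengths are in
#' expected substitutions per site, and malformed input fails loudly instead
#' of returning `NULL`.
#'
#' @param text A Newick string (single tree).
#' @param tree A `phylo` object.
#' @return `read_newick()` returns an [ape::phylo] object; `write_newick()`
#'   returns a single Newick string.
#' @examples
#' tr <- read_newick("((A:1,B:1)90:1,(C:1,D:1)80:1);")
#' tree_supports(tr)
#' write_newick(tr)
#' @export
read_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    abort("`text` must be a single Newick string.")
  }
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close) {
    abort(sprintf(
      "Malformed Newick: %d '(' vs %d ')' (unbalanced at position %d).",
      open, close, nchar(text)
    ))
  }
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Malformed Newick: ", conditionMessage(e)))
  )
  if (is.null(tr)) abort("Malformed Newick: parser returned no tree.")
  validate_tree(tr)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree) {
  validate_tree(tree)
  ape::write.tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("Expected an ape `phylo` object.")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0(
      "Duplicate leaf labels: ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")
    ))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    abort("Negative branch lengths are not allowed.")
  }
  invisible(tree)
}

#' Internal-node support values of a tree
#'
#' Parses `tree$node.label` to numeric support values (percent in \[0, 100\]);
#' empty or non-numeric labels become `NA`.
#'
#' @param tree A `phylo` object.
#' @return A numeric vector of length `tree$Nnode`, ordered as the internal
#'   nodes are numbered (root first).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!is.na(sup) & (sup < 0 | sup > 100)] <- NA_real_
  sup
}

#' Tip-label sets of all internal nodes
#'
#' @param tree A `phylo` object.
#' @return A named list (by internal node number) of character vectors of the
#'   tip labels descending from each internal node. The first element is the
#'   root (all tips).
#' @keywords internal
node_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  out <- lapply(pp, function(ix) tree$tip.label[ix])
  names(out) <- as.character(ntip + seq_along(out))
  out
}

#' Collapse poorly supported branches into polytomies
#'
#' Produces the support-condensed tree: every internal branch whose child
#' node's support is below `cutoff` is contracted, joining its children to
#' the parent node. Branches at or above the cutoff are untouched. Internal
#' nodes without a parseable support value are treated as unsupported and
#' collapsed (conservative: an unlabelled split never counts as evidence).
#' The collapsed branch's own length is discarded; condensation is a
#' topological operation used for congruence scoring and paralog vetting.
#'
#' @param tree A rooted or unrooted `phylo` with support values in
#'   `node.label` (see [tree_supports()]).
#' @param cutoff Support threshold in percent; branches with support
#'   `< cutoff` collapse. `cutoff = 0` is the identity on labelled trees.
#' @return A `phylo` object, possibly multifurcating.
#' @examples
#' tr <- read_newick("((A,B)30,(C,D)80);")
#' write_newick(condense_tree(tr, 50))
#' @export
condense_tree <- function(tree, cutoff = 50) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (nnode < 2L) return(tree)
  root <- ntip + 1L
  sup <- tree_supports(tree)

  parent <- integer(ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(NA_real_, ntip + nnode)
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length

  nodes <- (ntip + 1L):(ntip + nnode)
  drop <- rep(FALSE, ntip + nnode)
  if (cutoff > 0) {
    cand <- nodes[nodes != root]
    s <- sup[cand - ntip]
    drop[cand] <- is.na(s) | s < cutoff
  }
  if (!any(drop)) return(tree)

  newpar <- parent
  for (v in seq_len(ntip + nnode)) {
    if (v == root) next
    p <- parent[v]
    while (p != root && drop[p]) p <- parent[p]
    newpar[v] <- p
  }

  kept <- which(!drop & seq_len(ntip + nnode) != root)
  kept_internal <- c(root, kept[kept > ntip])
  map <- integer(ntip + nnode)
  map[seq_len(ntip)] <- seq_len(ntip)
  map[kept_internal] <- ntip + seq_along(kept_internal)

  children <- c(seq_len(ntip), setdiff(kept_internal, root))
  edge <- cbind(map[newpar[children]], map[children])
  out <- list(
    edge = edge,
    tip.label = tree$tip.label,
    Nnode = length(kept_internal),
    edge.length = if (!is.null(tree$edge.length)) elen[children]
  )
  if (is.null(tree$edge.length)) out$edge.length <- NULL
  if (!is.null(tree$node.label)) {
    out$node.label <- tree$node.label[kept_internal - ntip]
  }
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")
  out
}

#' Patristic distance matrix
#'
#' The patristic distance (PD) between two leaves is the sum of branch
#' lengths along the unique path connecting them.
#'
#' @param tree A `phylo` with branch lengths on every edge.
#' @return A symmetric numeric matrix (taxa x taxa, zero diagonal), in the
#'   branch-length units of the tree (substitutions/site).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' patristic_distances(tr)["A", "C"]
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) {
    abort("Tree has no branch lengths; patristic distances undefined.")
  }
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))
    abort(sprintf(
      "Missing branch length on edge(s) %s (parent->child: %s).",
      paste(bad, collapse = ", "),
      paste(apply(tree$edge[bad, , drop = FALSE], 1, paste, collapse = "->"),
            collapse = "; ")
    ))
  }
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Is a taxon set present as a clade/bipartition of a tree?
#'
#' Presence is judged on the unrooted bipartition: the set counts as present
#' if either it or its complement (within the tree's leaf set) is the tip set
#' of some edge. This makes the test independent of where the tree is rooted.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels (must all be in the tree).
#' @return `TRUE`/`FALSE`.
#' @export
clade_in_tree <- function(tree, taxa) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa, tips)
  if (length(unknown) > 0) {
    abort(paste0("Unknown taxa: ", paste(unknown, collapse = ", ")))
  }
  taxa <- sort(taxa)
  comp <- sort(setdiff(tips, taxa))
  if (length(taxa) <= 1L || length(comp) <= 1L) return(TRUE)
  for (cl in node_clades(tree)) {
    s <- sort(cl)
    if (identical(s, taxa) || identical(s, comp)) return(TRUE)
  }
  FALSE
}
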