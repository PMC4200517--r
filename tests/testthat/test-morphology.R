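test_that("the NEXUS reader handles symbols, missing, gaps and polymorphism", {
  path <- system.file("extdata", "synthetic_morph.nex", package = "phylomarkr")
  mm <- read_morph_nexus(path)
  expect_s3_class(mm, "morph_matrix")
  expect_equal(dim(mm), c(6L, 8L))
  expect_equal(unname(mm["Nymphaea", 5]), "?")
  expect_equal(unname(mm["Eudicot_sp", 5]), "?")   # gap folded into missing
  expect_equal(unname(mm["Chloranthus", 6]), "01") # polymorphic cell
  expect_equal(attr(mm, "ordered"), c(FALSE, TRUE, FALSE, TRUE, TRUE,
                                      FALSE, FALSE, FALSE))
  expect_equal(unname(attr(mm, "n_states")[1]), 2L)
})

test_that("the TSV fallback reads plain tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tc1\tc2", "A\t0\t01", "B\t1\t?", "C\t1\t2"), path)
  mm <- read_morph_tsv(path)
  expect_equal(dim(mm), c(3L, 2L))
  expect_equal(unname(mm["A", "c2"]), "01")
  expect_equal(attr(mm, "n_states"), c(c1 = 2L, c2 = 3L))
})

test_that("backbone enumeration counts follow the double factorial", {
  gr <- function(k) setNames(as.list(letters[1:k]), LETTERS[1:k])
  expect_length(enumerate_backbones(gr(3)), 3)
  expect_length(enumerate_backbones(gr(4)), 15)
  expect_length(enumerate_backbones(gr(5)), 105)
  expect_error(enumerate_backbones(list(A = "x", B = "x")), "disjoint")
})

test_that("enumerated backbones are pairwise distinct and carry subtrees", {
  groups <- list(Eud = c("e1", "e2", "e3"), Mono = c("m1", "m2"),
                 Mag = "g1", Chl = "c1", Cer = "r1")
  sub <- list(Eud = read_newick("((e1,e2),e3);"))
  bb <- enumerate_backbones(groups, subtrees = sub, outgroup = "OUT")
  expect_length(bb, 105)
  keys <- vapply(bb, function(tr) {
    paste(sort(vapply(node_clades_for_test(tr),
                      function(cl) paste(sort(cl), collapse = ","),
                      character(1))), collapse = "|")
  }, character(1))
  expect_equal(length(unique(keys)), 105L)
  for (tr in bb[c(1, 50, 105)]) {
    expect_setequal(tr$tip.label,
                    c("e1", "e2", "e3", "m1", "m2", "g1", "c1", "r1", "OUT"))
    expect_true(clade_in_tree(tr, c("e1", "e2")))      # fixed subtree kept
    expect_true(clade_in_tree(tr, c("e1", "e2", "e3")))
  }
})

test_that("the published five-lineage arrangements occur among the 105", {
  tsv <- system.file("extdata", "published_backbones.tsv",
                     package = "phylomarkr")
  pub <- read.delim(tsv)
  expect_equal(nrow(pub), 15L)
  groups <- list(Cerato = "Cerato", Chlor = "Chlor", Eud = "Eud",
                 Magnol = "Magnol", Mono = "Mono")
  bb <- enumerate_backbones(groups, outgroup = "Out")
  keys <- vapply(bb, function(tr) {
    paste(sort(vapply(node_clades_for_test(tr),
                      function(cl) paste(sort(cl), collapse = ","),
                      character(1))), collapse = "|")
  }, character(1))
  for (nwk in pub$topology) {
    tr <- read_newick(nwk)
    key <- paste(sort(vapply(node_clades_for_test(tr),
                             function(cl) paste(sort(cl), collapse = ","),
                             character(1))), collapse = "|")
    expect_true(key %in% keys)
  }
})

test_that("quartet step counts match the single- and double-change cases", {
  tr <- read_newick("((A,B),(C,D));")
  one <- morph_matrix(matrix(c("0", "0", "1", "1"), 4, 1,
                             dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(parsimony_steps(one, tr)$total, 1)

  two <- morph_matrix(matrix(c("0", "1", "0", "1"), 4, 1,
                             dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(parsimony_steps(two, tr)$total, 2)
})

test_that("Fitch and Sankoff match exhaustive minimisation on random cases", {
  set.seed(61)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- NULL
    k <- sample(2:3, 1)
    st <- sample(0:(k - 1), n, replace = TRUE)
    cells <- setNames(as.character(st), tr$tip.label)
    b <- brute_parsimony(tr, st, k)
    expect_equal(fitch_steps(tr, cells, k), b)
    expect_equal(sankoff_steps(tr, cells, k), b)
  }
})

test_that("ordered characters pay ladder costs under Sankoff", {
  tr <- read_newick("((A,B),(C,D));")
  cells <- c(A = "0", B = "0", C = "2", D = "2")
  expect_equal(sankoff_steps(tr, cells, 3, abs(outer(0:2, 0:2, "-"))), 2)
  expect_equal(sankoff_steps(tr, cells, 3), 1)  # unordered: one jump

  mm <- morph_matrix(matrix(c("0", "0", "2", "2"), 4, 2,
                            dimnames = list(c("A", "B", "C", "D"), NULL)),
                     ordered = c(FALSE, TRUE))
  ps <- parsimony_steps(mm, tr)
  expect_equal(ps$per_character$steps, c(1L, 2L))
  expect_equal(ps$total, 3)
})

test_that("missing and polymorphic cells use their state sets freely", {
  tr <- read_newick("((A,B),(C,D));")
  mm <- morph_matrix(matrix(c("0", "?", "1", "1"), 4, 1,
                            dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(parsimony_steps(mm, tr)$total, 1)

  poly <- morph_matrix(matrix(c("01", "0", "1", "1"), 4, 1,
                              dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_equal(parsimony_steps(poly, tr)$total, 1)

  uninf <- morph_matrix(matrix(c("0", "0", "0", "?"), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  ps <- parsimony_steps(uninf, tr)
  expect_equal(ps$total, 0)
  expect_false(ps$per_character$informative)
})

test_that("Fitch totals are invariant under re-rooting", {
  set.seed(62)
  for (i in 1:10) {
    tr <- ape::rtree(7)
    st <- sample(0:2, 7, replace = TRUE)
    cells <- setNames(as.character(st), tr$tip.label)
    s0 <- fitch_steps(tr, cells, 3)
    rr <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[i %% 7 + 1],
                    resolve.root = TRUE)
    expect_equal(fitch_steps(rr, cells, 3), s0)
  }
})

test_that("taxa absent from the tree are ignored, unknown tips rejected", {
  tr <- read_newick("((A,B),(C,D));")
  mm <- morph_matrix(matrix("0", 5, 1,
                            dimnames = list(c("A", "B", "C", "D", "E"), NULL)))
  expect_equal(parsimony_steps(mm, tr)$total, 0)
  mm4 <- morph_matrix(matrix("0", 3, 1, dimnames = list(c("A", "B", "C"), NULL)))
  expect_error(parsimony_steps(mm4, tr), "not in matrix")
})

test_that("the enumerated optimum is a lower envelope of all backbones", {
  st <- simulate_species_tree(5, seed = 70)
  mm <- simulate_morphology(st, n_chars = 20, n_states = 3, rate = 2, seed = 71)
  groups <- setNames(as.list(st$tip.label), paste0("L", 1:5))
  bb <- enumerate_backbones(groups)
  # rename placeholder tips back to the taxa
  report <- backbone_steps(mm, bb)
  expect_equal(nrow(report), 105L)
  expect_true(all(report$steps >= report$steps[1]))
  expect_true(!is.unsorted(report$steps))
})
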