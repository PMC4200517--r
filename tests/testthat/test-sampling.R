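test_that("the default subsampling design yields 580 seeded subsets", {
  genes <- sprintf("g%02d", 1:59)
  d <- draw_subsets(genes, seed = 42)
  expect_equal(nrow(d), 580L)
  expect_equal(sort(unique(d$n_genes)), seq(2, 58, by = 2))
  expect_true(all(vapply(seq_len(nrow(d)), function(i) {
    g <- d$genes[[i]]
    length(g) == d$n_genes[i] && !anyDuplicated(g)
  }, logical(1))))

  d2 <- draw_subsets(genes, seed = 42)
  expect_identical(d$genes, d2$genes)
  d3 <- draw_subsets(genes, seed = 43)
  expect_false(identical(d$genes, d3$genes))
})

test_that("subsets at the full gene count are the complete set", {
  genes <- paste0("g", 1:6)
  d <- draw_subsets(genes, counts = 6, replicates = 4, seed = 1)
  for (g in d$genes) expect_setequal(g, genes)
  expect_error(draw_subsets(genes, counts = 7), "\\[1, 6\\]")
})

test_that("NJ recovers the generating topology from additive distances", {
  set.seed(99)
  for (i in 1:50) {
    tr <- ape::rtree(sample(5:10, 1))
    d <- patristic_distances(tr)  # exactly additive on the tree
    nj <- ape::nj(as.dist(d))
    expect_true(same_topology(nj, tr))
  }
})

test_that("the internal backend handles 3 taxa and flags saturation", {
  m <- as_msa(c(a = "AAAA", b = "AAAT", c = "AATT"))
  tr <- infer_tree(m, bootstrap_reps = 0)
  expect_equal(ape::Ntip(tr), 3L)

  sat <- as_msa(c(a = "AAAA", b = "RRRR", c = "KKKK", d = "LLLL"))
  expect_error(infer_tree(sat, bootstrap_reps = 0), "saturation")
})

test_that("clean long alignments put high bootstrap on all true splits", {
  ok <- 0
  for (s in 1:10) {
    tr <- simulate_species_tree(8, seed = 100 + s)
    al <- simulate_alignment(tr, columns = 3000, seed = 200 + s)
    est <- infer_tree(al, bootstrap_reps = 100, seed = s)
    sup <- suppressWarnings(as.numeric(est$node.label))
    all_found <- same_topology(est, tr)
    if (all_found && all(sup >= 95, na.rm = TRUE)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("a function backend is used verbatim", {
  fixed <- read_newick("((a,b),(c,d));")
  out <- infer_tree(as_msa(c(a = "A")), backend = function(msa, seed) fixed)
  expect_identical(out, fixed)
})

test_that("recovery curves count bipartition presence per gene count", {
  t_yes <- read_newick("((A,B),(C,D),E);")
  t_no <- read_newick("((A,C),(B,D),E);")
  trees <- tibble::tibble(
    n_genes = rep(c(2L, 4L), each = 4),
    replicate = rep(1:4, 2),
    tree = c(list(t_yes, t_yes, t_no, t_yes), rep(list(t_yes), 4))
  )
  rc <- recovery_curve(trees, clades = list(AB = c("A", "B")))
  expect_equal(rc$prop, c(0.75, 1))
  g <- glance(rc)
  expect_equal(g$first_full, 4L)
  expect_equal(g$sustained_full, 4L)

  rc0 <- recovery_curve(trees, clades = list(AC = c("A", "C")))
  expect_equal(rc0$prop, c(0.25, 0))
  expect_true(is.na(glance(rc0)$first_full))

  expect_error(recovery_curve(trees, clades = list(bad = c("A", "ZZZ"))),
               "Unknown taxa")
})

test_that("sustained recovery ignores single-point flukes", {
  curve <- tibble::tibble(
    clade = "x",
    n_genes = c(2L, 4L, 6L, 8L),
    n_trees = 4L,
    n_recovered = c(4L, 2L, 4L, 4L),
    prop = c(1, 0.5, 1, 1)
  )
  class(curve) <- c("recovery_curve", class(curve))
  g <- glance(curve)
  expect_equal(g$first_full, 2L)
  expect_equal(g$sustained_full, 6L)
})

test_that("recovery is non-decreasing without discordance (allowing one dip)", {
  for (s in 1:3) {
    cfg <- sim_config(seed = 300 + s, n_taxa = 8, n_genes = 10, k = 0,
                      columns = 150)
    b <- sim_bundle(cfg)
    alignments <- setNames(b$genes$alignment, b$genes$gene)
    d <- draw_subsets(names(alignments), counts = c(2, 4, 8), replicates = 6,
                      seed = s)
    d$tree <- lapply(seq_len(nrow(d)), function(i) {
      sm <- concatenate(alignments[d$genes[[i]]],
                        taxa = b$species_tree$tip.label)
      infer_tree(sm$msa, bootstrap_reps = 0)
    })
    clades <- Filter(function(x) length(x) %in% 2:6, b$truth$clades)
    rc <- recovery_curve(d, clades = clades[1])
    dips <- sum(diff(rc$prop) < 0)
    expect_lte(dips, 1)
  }
})

test_that("ranked accumulation builds nested prefix matrices", {
  al <- lapply(1:6, function(i) {
    as_msa(matrix(LETTERS[i], 2, 10 * i, dimnames = list(c("x", "y"), NULL)))
  })
  names(al) <- paste0("g", 1:6)
  ranked <- c("g3", "g1", "g5", "g2", "g4", "g6")
  sms <- ranked_accumulation(al, ranked, steps = c(2, 4))
  expect_named(sms, c("top2", "top4"))
  expect_equal(glance(sms$top2)$n_columns, 40)   # g3 + g1
  expect_equal(glance(sms$top4)$n_columns, 110)  # + g5 + g2
  # prefix property
  p2 <- tidy(sms$top2)
  p4 <- tidy(sms$top4)
  expect_equal(p2, p4[1:2, ], ignore_attr = TRUE)
  expect_identical(sms$top2$msa, sms$top4$msa[, 1:40])

  full <- ranked_accumulation(al, ranked, steps = 6)
  expect_equal(glance(full$top6)$n_genes, 6)
  expect_error(ranked_accumulation(al, ranked, steps = c(4, 2)), "ascending")
  expect_error(ranked_accumulation(al, ranked, steps = 7), "exceeds")
})
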