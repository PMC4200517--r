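make_og_table <- function() {
  # 10 OGs, 5 species, mixed coverage/lengths
  set.seed(17)
  rows <- list()
  for (og in sprintf("OG%02d", 1:10)) {
    for (sp in paste0("s", 1:5)) {
      if (runif(1) < 0.75) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          og = og, species = sp, length = sample(40:120, 1))
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("filter_ogs applies the coverage x relative-length rule", {
  tab <- tibble::tibble(
    og = rep(c("OG1", "OG2"), c(5, 3)),
    species = c(paste0("s", 1:5), paste0("s", 1:3)),
    length = c(rep(100, 5), rep(100, 3))
  )
  refs <- tibble::tibble(og = c("OG1", "OG2"), ref_length = c(100, 100))
  res <- filter_ogs(tab, refs, species = paste0("s", 1:5))
  expect_true(res$kept[res$og == "OG1"])    # 5/5 at full length
  expect_false(res$kept[res$og == "OG2"])   # 3/5 < 0.8
})

test_that("coverage threshold is inclusive and short sequences drop out", {
  tab <- tibble::tibble(og = "OG1", species = paste0("s", 1:5),
                        length = c(100, 100, 100, 100, 79))
  refs <- tibble::tibble(og = "OG1", ref_length = 100)
  res <- filter_ogs(tab, refs, species = paste0("s", 1:5))
  expect_equal(res$n_retained, 4L)   # the 79-residue copy fails 0.8 x 100
  expect_equal(res$coverage, 0.8)
  expect_true(res$kept)              # >= is inclusive

  res2 <- filter_ogs(tab, refs, species = paste0("s", 1:6))
  expect_false(res2$kept)            # 4/6 < 0.8
})

test_that("filter_ogs equals exhaustive rule application on a toy table", {
  tab <- make_og_table()
  refs <- tibble::tibble(og = sprintf("OG%02d", 1:10), ref_length = 100)
  res <- filter_ogs(tab, refs, species = paste0("s", 1:5))
  for (og in refs$og) {
    sub <- tab[tab$og == og, ]
    n_ret <- sum(sub$length >= 80)
    expect_equal(res$n_retained[res$og == og], n_ret)
    expect_equal(res$kept[res$og == og], n_ret / 5 >= 0.8)
  }
  # row-order invariance
  res_sh <- filter_ogs(tab[sample(nrow(tab)), ], refs, species = paste0("s", 1:5))
  expect_identical(res, res_sh)
})

test_that("missing reference lengths are reported by OG id", {
  tab <- tibble::tibble(og = "OGX", species = "s1", length = 100)
  expect_error(filter_ogs(tab, tibble::tibble(og = "OGY", ref_length = 1)),
               "OGX")
})

test_that("hidden-paralog vetting excludes supported mixed clades only", {
  groups <- list(monocots = c("m1", "m2"), eudicots = c("e1", "e2"))

  clean <- read_newick("(((m1,m2)100,(e1,e2)100)100,(o1,o2)100);")
  expect_equal(vet_gene_tree(clean, groups)$verdict, "selected")

  mixed <- read_newick("(((m1,e1)95,(m2,e2)95)95,(o1,o2)95);")
  v <- vet_gene_tree(mixed, groups)
  expect_equal(v$verdict, "excluded")
  expect_setequal(v$offending_clade[[1]], c("m1", "e1"))

  # same conflict but unsupported: condensation removes it
  weak <- read_newick("(((m1,e1)30,(m2,e2)30)30,(o1,o2)30);")
  expect_equal(vet_gene_tree(weak, groups)$verdict, "selected")

  # a clade containing one complete group plus part of another is nesting,
  # not hidden paralogy
  nested <- read_newick("((((m1,m2)100,e1)100,e2)100,(o1,o2)100);")
  expect_equal(vet_gene_tree(nested, groups)$verdict, "selected")

  expect_error(vet_gene_tree(clean, list(g1 = c("zz1", "zz2"))), "No leaves")
})

test_that("vet verdicts are invariant to tree rotation", {
  groups <- list(a = c("m1", "m2"), b = c("e1", "e2"))
  mixed <- read_newick("(((m1,e1)95,(m2,e2)95)95,(o1,o2)95);")
  rot <- ape::rotateConstr(mixed, rev(mixed$tip.label))
  expect_equal(vet_gene_tree(mixed, groups)$verdict,
               vet_gene_tree(rot, groups)$verdict)
})

test_that("congruence scoring follows the +1/-1/0 trichotomy", {
  sp <- read_newick("(((A,B),(C,D)),(E,F));")

  perfect <- read_newick("(((A,B)100,(C,D)100)100,(E,F)100);")
  g <- glance(score_congruence(perfect, sp))
  expect_equal(g$total, 6L)
  expect_equal(g$n_congruent, 6L)

  star <- read_newick("(((A,B)10,(C,D)10)10,(E,F)10);")
  expect_equal(glance(score_congruence(star, sp))$total, 0L)

  # hand evaluation: swapping B and C between the two cherries makes the
  # smallest containing clade of A, B, C and D all conflict; E and F keep
  # their congruent cherry
  swapped <- read_newick("(((A,C)90,(B,D)90)90,(E,F)90);")
  rep <- score_congruence(swapped, sp)
  scores <- setNames(rep$score, rep$taxon)
  expect_equal(unname(scores[c("A", "B", "C", "D")]), rep(-1L, 4))
  expect_equal(unname(scores[c("E", "F")]), c(1L, 1L))
  expect_equal(attr(rep, "total"), -2L)

  expect_error(score_congruence(read_newick("((A,B)90,X)90;"), sp), "4 shared")
})

test_that("scoring only uses taxa shared with the species tree", {
  sp <- read_newick("(((A,B),(C,D)),(E,F));")
  extra <- read_newick("((((A,Z1)100,B)100,(C,D)100)100,(E,F)100);")
  g <- glance(score_congruence(extra, sp))
  expect_equal(g$n_shared, 6L)
  expect_equal(g$total, 6L)  # Z1 dropped; restriction is congruent
})

test_that("gene ranking is descending with lexicographic tie-break", {
  reports <- tibble::tibble(gene = c("g1", "g2", "g3"),
                            total = c(10L, -2L, 10L))
  r <- rank_genes(reports)
  expect_equal(r$gene, c("g1", "g3", "g2"))
  expect_equal(r$rank, 1:3)

  expect_equal(rank_genes(tibble::tibble(gene = "g9", total = 0L))$gene, "g9")
  expect_error(rank_genes(tibble::tibble(gene = c("a", "a"), total = c(1L, 2L))),
               "Duplicate")

  # top-k extraction from a ranked list of 59
  many <- tibble::tibble(gene = sprintf("g%02d", 1:59),
                         total = rev(seq_len(59)))
  top16 <- head(rank_genes(many)$gene, 16)
  expect_length(top16, 16)
  expect_equal(top16, sprintf("g%02d", 1:16))
})

test_that("paralog pruning keeps the shortest copy with a stable tie-break", {
  tr <- read_newick("((x1:0.1,x2:0.3):1,(y1:1,z1:1):1);")
  pruned <- prune_shortest_paralog(tr, c(x1 = "X", x2 = "X", y1 = "Y", z1 = "Z"))
  expect_setequal(pruned$tip.label, c("x1", "y1", "z1"))

  nodup <- read_newick("((a:1,b:1):1,c:1);")
  same <- prune_shortest_paralog(nodup, c(a = "A", b = "B", c = "C"))
  expect_identical(write_newick(same), write_newick(nodup))

  tie <- read_newick("((x1:0.2,x2:0.2):1,(y1:1,z1:1):1);")
  kept <- prune_shortest_paralog(tie, c(x1 = "X", x2 = "X", y1 = "Y", z1 = "Z"))
  expect_true("x1" %in% kept$tip.label)  # first in tip order wins
  expect_false("x2" %in% kept$tip.label)
})

test_that("mean congruence decreases under growing NNI discordance", {
  st <- simulate_species_tree(12, seed = 20)
  means <- vapply(c(0, 2, 8), function(k) {
    gts <- simulate_gene_trees(st, 25, "nni", k = k, seed = 21)
    mean(score_genes(gts, st)$total)
  }, numeric(1))
  expect_true(means[1] > means[2] && means[2] > means[3])
})
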