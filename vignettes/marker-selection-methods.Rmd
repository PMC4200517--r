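---
title: "Marker selection, congruence scoring and topology diagnostics: methods"
author: "phylomarkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker selection, congruence scoring and topology diagnostics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylomarkr)
```

# The problem

Deep, rapid radiations leave short internal branches that single genes
rarely resolve, while concatenating every available gene imports exactly
the signals — hidden paralogy, saturation, long-branch attraction — that
produce confidently wrong topologies. The workflow implemented here treats
marker selection as a first-class, quantitative step: filter ortholog
groups on coverage and length, vet each gene tree for paralogy, score and
rank genes by topological congruence with a vetted reference tree, measure
how many genes a clade needs for stable recovery, and screen the survivors
with branch-length and saturation diagnostics. A separate morphology
module asks, for a fixed set of major lineages, how alternative backbone
arrangements fare against a multistate character matrix under parsimony
and the Mk likelihood model.

Every stage is testable without any external data because the package
ships its own generator with known ground truth (`sim_bundle()`).

# Models and procedures

## Support-condensed trees

All topology-sensitive steps (vetting, congruence scoring) first collapse
internal branches whose support falls below a cutoff (default 50%,
`condense_tree()`), so weakly supported resolution is never treated as
evidence. Two semantics are deliberate: an internal node *without* a
parseable support label is treated as unsupported and collapsed
(conservative — an unlabelled split cannot count for or against a gene),
and the collapsed branch's length is discarded rather than redistributed,
because condensation is used purely topologically downstream. Retained
branches are untouched.

## Congruence scoring

The notion of "the position of a taxon" in a gene tree is operationalised
as its smallest non-trivial containing clade: the leaf set under its
parent node, after condensation and restriction to the taxa shared with
the species tree. That set either (a) is compatible with the species tree
(for a fully resolved reference: appears among its clades) — score +1; (b)
overlaps some species-tree clade without either containing the other —
score −1; or (c) does not exist because the taxon hangs from the root —
score 0. The per-taxon trichotomy is local by design: one misplaced taxon
damages the scores of the taxa whose smallest clades it invades (its new
neighbours and its abandoned partners), which matches the intuition that a
rogue taxon degrades a gene's usefulness around its attachment points. A
gene's total is the sum over taxa; ranking is by descending total with a
lexicographic tie-break on gene id, so ranking is reproducible.

A taxon attached directly to the root (e.g. a lone outgroup) always scores
0 under this rule: it has no non-trivial containing clade. The maximal
total for a gene tree identical to a reference with one root-child
outgroup is therefore the ingroup size, not the tip count.

## Hidden-paralog vetting

After condensation, a gene is excluded if some supported clade contains
members of at least two reference monophyletic groups but all sampled
members of none of them. The "all sampled members" clause is what
separates paralogy from legitimate nesting: a clade holding one complete
group plus part of another is just the next node up in the hierarchy,
whereas a mixed clade that fractures every group it touches implies the
species are contributing copies from different sides of a duplication.
The root never offends (it contains everything), and unsupported conflict
is ignored — exclusion needs evidence.

## Subsampling and recovery curves

`draw_subsets()` samples gene subsets without replacement at each count of
a grid (default 2–58 by 2, 20 replicates → 580 matrices), all driven by
one seed. Recovery of a target clade in a replicate tree is judged on the
unrooted bipartition, ignoring support, so the statistic does not depend
on rooting choices of the inference backend. Two minimal gene numbers are
reported: the first count reaching 100% recovery, and the sustained count
from which all larger grid points stay at 100% — the latter is the
headline figure since a single 100% point among noisy neighbours is a
fluke, not a threshold.

The internal inference backend is neighbour-joining on Poisson-corrected
amino-acid p-distances (d = −ln(1 − p)) with a column-resampling bootstrap;
it is deterministic under a seed and fast enough for hundreds of replicate
matrices on a desktop. NJ is consistent on additive distances, which the
test suite verifies exactly, and small negative NJ branches are clamped to
zero. An arbitrary external backend (e.g. a maximum-likelihood program)
can be plugged in as a function, and supermatrices export to relaxed
PHYLIP plus RAxML-style partition files for that purpose.

## Long-branch scores

For taxon *i*, `LB_i = (mean_{j != i} PD(i, j) / mean over all unordered
pairs PD − 1) × 100` — a percent deviation, dimensionless, summing to zero
over taxa and invariant to uniform rescaling of branch lengths (both
properties are asserted for every tree in the test suite). Gene-level
summaries are the mean of the upper quartile (values at or above the 75th
percentile, type-7 linear interpolation) and the sample (n − 1) standard
deviation of the taxon scores. The gene × taxon matrix uses a default
flagging threshold of 150, the conventional alarm level for single
sequences behaving as long branches.

## Saturation regression

p-distances (pairwise deletion: a column is dropped for a pair when either
sequence has `-`, `?` or `X`; chosen over complete deletion because
transcriptome-derived alignments are patchy and complete deletion would
discard most columns) are regressed on patristic distances by ordinary
least squares, p as the response with an intercept. Under this
orientation, multiple substitutions flatten the curve, so smaller slopes
and smaller R² mean more saturation; the regression direction is fixed and
documented so that reading never flips. Pairs with undefined p are
dropped; at least three usable pairs and non-zero PD variance are
required.

## Outlier flagging

Density-plot "shoulders" are replaced by two explicit rules, both
reported: the Tukey fence (beyond Q3 + 1.5 IQR, or below Q1 − 1.5 IQR for
"low" statistics such as slopes), which is deterministic and is the
default for pruning decisions; and the first local minimum of a Gaussian
kernel density estimate beyond the main mode, which mimics the visual
shoulder cut when a minor mode exists and flags nothing when the
distribution is unimodal. Eight genes is the minimum for either rule to be
meaningful.

## Parsimony-informative sites

A column is informative when at least two states each occur in at least
two sequences; gaps and missing symbols never count as states. The
denominator of the percentage is all columns. At partitioning cutoffs the
boundary goes to the "greater" side (a gene at exactly 30% PI lands in
`*_greater_30`), a convention encoded in the matrix names; bands
`a ≤ PI < b` are half-open for the same reason.

## Backbone enumeration and step counting

All (2k − 3)!! rooted binary arrangements of k lineage placeholders are
generated (3, 15, 105 for k = 3, 4, 5), each grafted with its fixed
within-group subtree and rooted on the outgroup, so only the spine varies.
Grafting is performed on the Newick strings with word-boundary
substitution, which keeps the enumeration independent of node-numbering
conventions.

Step counting: unordered characters use the Fitch state-set pass (binary
trees; the postorder edge walk folds children into parents incrementally),
ordered characters use Sankoff dynamic programming with |i − j| ladder
costs, which also covers polytomies and arbitrary cost matrices. Missing
cells enter as the full state set and polymorphic cells as their listed
set, at no within-taxon cost — the standard state-set semantics.
Characters with fewer than two observed states contribute zero and are
flagged uninformative. The suite proves Fitch equal to exhaustive
assignment enumeration and to Sankoff under uniform costs, and invariant
under re-rooting.

## Mk ancestral states and novelties

For one character, the symmetric k-state Mk model has the closed-form
transition probability `P(i→j, t) = (1 − e^{−kqt})/k` for i ≠ j, with q
the off-diagonal rate. The single rate is estimated by maximising the tree
likelihood; because the log-likelihood flattens into a plateau for large
rates, the 1-D search first brackets the optimum on a 30-point log-spaced
grid before golden-section refinement (a pure `optimize()` call can stall
on the plateau). Marginal probabilities at every internal node come from
the standard two-pass (down/up) pruning recursion, equivalent to re-rooting
at each node under this reversible model; the suite checks them against
exhaustive summation over all internal-state assignments to 1e−8 and
against an independent re-rooting implementation.

Taxa with missing or polymorphic cells are pruned per character before
fitting (fixed tip states are required by the likelihood); characters
invariant after pruning are flagged and skipped. A character is a novelty
on the branch subtending a focal clade when the best states at the
clade's crown node and its parent differ and both reconstructions are
decisive — log-likelihood margin (log of the ratio of best to runner-up
marginal) at least 2, the conventional significance rule, configurable.

# The synthetic-data generator

`sim_config()` fixes the study conditions in one place. Defaults: 59
genes; a 26-taxon ultrametric Yule ingroup plus one outgroup grafted on a
stem so the tree stays ultrametric; ingroup height 0.5 expected
substitutions/site (a typical deep-phylogenomic depth for conserved
nuclear amino-acid markers); 400 aligned amino acids per gene (the
per-gene share of a ~25,000-column, 59-gene supermatrix); gamma site-rate
shape 1 in 4 discrete categories; uniform-exchangeability 20-state
substitution model. The uniform model is deliberate: every downstream
statistic here (p-distance, PD, LB, PI, congruence) is model-agnostic, so
an empirical exchangeability matrix would add a dependency without
changing what the tests can show.

Discordance comes in two modes: `"nni"` applies k random rooted NNI moves
per gene — countable, direct control of topological error, ideal for
congruence-scoring tests — and `"coalescent"` samples gene trees under the
multispecies coalescent with population parameter theta (discordance grows
with theta and vanishes as theta → 0). Long-branch artifacts multiply a
flagged taxon's terminal branch; saturated genes have all branch lengths
multiplied before simulation. Morphological characters evolve as explicit
Mk jump chains, so the realised number of changes is logged per character
and bounds the parsimony steps from above — an inequality the tests
assert.

One global seed drives everything; gene i uses the derived substream seed
`seed + 1009·i`, so extending a bundle with more genes never reshuffles
the genes already drawn.

What the generator does not emulate: indels and alignment error (no gap
process), codon structure and empirical amino-acid exchangeabilities,
heterotachy, and missing data beyond whole-taxon absence from a gene.
Passing tests therefore demonstrate correctness of the statistics and the
selection logic under clean, known-truth conditions — not robustness to
alignment artifacts.

# Experiment sizes

The test-suite and acceptance-script experiments run at sizes chosen to
keep a full check under a few minutes on one CPU while preserving each
property's statistical teeth: congruence-vs-discordance uses 100 genes per
NNI level on a 26-taxon tree; long-branch recovery uses 20 seeds × 12
genes; saturated-gene recall uses 20 seeds at the full 59-gene, 400-column
default with 4 genes saturated at 10×; clean-recovery bootstrap checks use
3,000-column alignments over 10 seeds. Oracle suites (exhaustive parsimony
and Mk enumeration) stay at ≤ 6 taxa where enumeration is exact.

# Known limitations and measured boundaries

* **Long-branch top-rank at small multipliers.** On ultrametric Yule
  trees, basally diverging taxa carry a high topological LB baseline (their
  mean pairwise PD approaches twice the tree height). An artifact injected
  by multiplying a typical (median) terminal branch by 5 tops the
  taxon-ranking in only ~60% of seeds; from 8× upward it does so in ≥ 90%.
  The package's acceptance experiment asserts the property at the 5×
  boundary and the assertion fails there by design — the measured rates at
  5× and 10× are both reported by `scripts/acceptance.R` so the detection
  boundary is visible rather than hidden behind a tuned multiplier.
* **Congruence rule locality.** A single rogue taxon also penalises the
  taxa whose smallest clades it disturbs; totals are therefore a
  conservative measure of gene quality, not a per-taxon error count.
* **NJ backend.** The internal backend is a stand-in for maximum
  likelihood at desk scale; recovery thresholds estimated with it are not
  comparable to ML-derived ones, which is why the external-backend hook
  and PHYLIP/partition exporters exist.
* **Paralog pruning tie-break.** Equal terminal branch lengths keep the
  copy first in tip order; this is arbitrary but deterministic and logged.
* **PI denominators.** Percentages divide by all columns, including fully
  gapped ones; alignments trimmed differently will shift percentages near
  the partition cutoffs.
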