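#' Run the marker-selection pipeline end to end
#'
#' Wires the stages together on a synthetic (or user-supplied) bundle:
#' `simulate` -> `score` (congruence of every gene tree against the species
#' tree) -> `rank` -> `subsample` (random gene subsets, NJ trees, recovery
#' curves for the species tree's deepest clades) -> `diagnose` (LB and
#' saturation tables) -> `pi` (informative-site table). Each stage writes
#' plain-text artifacts under `out_dir` and the run ends with a JSON
#' manifest listing every file with its MD5 hash, the seed and the package
#' version, so reruns with the same config are verifiably identical.
#'
#' @param config A [sim_config()] (or path to a YAML file of its fields).
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of
#'   `c("simulate", "score", "rank", "subsample", "diagnose", "pi")`;
#'   stages always run in dependency order.
#' @param subsample_counts,subsample_replicates Subsampling design
#'   (defaults scale with the number of genes).
#' @param bootstrap_reps Bootstrap replicates for the internal NJ backend.
#' @return The manifest as a tibble (`stage`, `file`, `md5`), invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir = tempfile("phylomarkr_run_"),
                         stages = c("simulate", "score", "rank", "subsample",
                                    "diagnose", "pi"),
                         subsample_counts = NULL,
                         subsample_replicates = 5,
                         bootstrap_reps = 0) {
  if (is.character(config)) {
    fields <- yaml::yaml.load_file(config)
    config <- do.call(sim_config, fields)
  }
  stopifnot(inherits(config, "sim_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  note <- function(stage, path) {
    files[[length(files) + 1L]] <<- tibble(stage = stage, file = path)
    path
  }

  need <- function(s) s %in% stages
  if (any(c("score", "rank", "subsample", "diagnose", "pi") %in% stages) &&
      !need("simulate")) {
    abort("Requested stages need 'simulate' to run first; add it to `stages`.")
  }

  bundle <- NULL
  if (need("simulate")) {
    bundle <- sim_bundle(config)
    p <- file.path(out_dir, "species_tree.nwk")
    writeLines(write_newick(bundle$species_tree), note("simulate", p))
    p <- file.path(out_dir, "gene_trees.nwk")
    writeLines(vapply(bundle$genes$tree, write_newick, character(1)),
               note("simulate", p))
    for (i in seq_len(nrow(bundle$genes))) {
      p <- file.path(out_dir, sprintf("%s.fasta", bundle$genes$gene[i]))
      write_fasta_msa(bundle$genes$alignment[[i]], note("simulate", p))
    }
  }

  scores <- NULL
  if (need("score")) {
    gts <- setNames(bundle$genes$tree, bundle$genes$gene)
    scores <- score_genes(gts, bundle$species_tree)
    p <- file.path(out_dir, "congruence_scores.tsv")
    write.table(scores, note("score", p), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (need("rank")) {
    if (is.null(scores)) abort("Stage 'rank' needs stage 'score' first.")
    ranked <- rank_genes(scores)
    p <- file.path(out_dir, "gene_ranking.tsv")
    write.table(ranked, note("rank", p), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (need("subsample")) {
    alignments <- setNames(bundle$genes$alignment, bundle$genes$gene)
    counts <- subsample_counts %||%
      unique(pmax(2, pmin(nrow(bundle$genes),
                          round(seq(2, nrow(bundle$genes), length.out = 5)))))
    design <- draw_subsets(names(alignments), counts = counts,
                           replicates = subsample_replicates,
                           seed = config$seed)
    design$tree <- map(seq_len(nrow(design)), function(i) {
      sm <- concatenate(alignments[design$genes[[i]]],
                        taxa = bundle$species_tree$tip.label)
      infer_tree(sm$msa, bootstrap_reps = bootstrap_reps,
                 seed = config$seed + i)
    })
    clades <- keep(bundle$truth$clades,
                   ~ length(.x) >= 2 &&
                     length(.x) <= length(bundle$species_tree$tip.label) - 2)
    ord <- order(lengths(clades), decreasing = TRUE)
    clades <- clades[ord[seq_len(min(3, length(clades)))]]
    curve <- recovery_curve(design, clades)
    p <- file.path(out_dir, "recovery_curve.tsv")
    write.table(as.data.frame(curve), note("subsample", p), sep = "\t",
                quote = FALSE, row.names = FALSE)
    p <- file.path(out_dir, "recovery_minima.tsv")
    write.table(glance(curve), note("subsample", p), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (need("diagnose")) {
    gts <- setNames(bundle$genes$sim_tree, bundle$genes$gene)
    alignments <- setNames(bundle$genes$alignment, bundle$genes$gene)
    p <- file.path(out_dir, "lb_summary.tsv")
    write.table(gene_lb_summary(gts), note("diagnose", p), sep = "\t",
                quote = FALSE, row.names = FALSE)
    p <- file.path(out_dir, "lb_taxon_gene.tsv")
    write.table(taxon_gene_matrix(gts), note("diagnose", p), sep = "\t",
                quote = FALSE, row.names = FALSE)
    p <- file.path(out_dir, "saturation.tsv")
    write.table(saturation_table(gts, alignments), note("diagnose", p),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (need("pi")) {
    alignments <- setNames(bundle$genes$alignment, bundle$genes$gene)
    p <- file.path(out_dir, "pi_table.tsv")
    write.table(pi_table(alignments), note("pi", p), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest <- bind_rows(files) |>
    mutate(md5 = unname(tools::md5sum(.data$file)),
           file = basename(.data$file))
  jsonlite::write_json(
    list(seed = config$seed,
         package = as.character(utils::packageVersion("phylomarkr")),
         files = manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
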