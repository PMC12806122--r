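#' Run the full promoter-design pipeline
#'
#' For each dataset: motif enrichment of target vs background peaks; then
#' intersection of significantly enriched motifs across all datasets; then
#' one tandem-array promoter design per conserved motif. Writes per-dataset
#' enrichment TSVs, the conserved-set TSV, a design summary TSV, one
#' GenBank file per design, the exported inputs, and a JSON manifest
#' (package version, configuration echo, seed, input checksums). All
#' outputs are deterministic for a fixed input + seed.
#'
#' @param datasets A [simulate_study()] result, or a list of
#'   `list(target = , background = )` pairs where each element is a
#'   [peak_set()] with sequences or a FASTA path.
#' @param library Motif library: named list of [pwm()], or a motif file
#'   path readable by [read_motifs()] (JASPAR dialect assumed).
#' @param out_dir Run directory (created; must not already contain a
#'   manifest).
#' @param fc_min,fdr_max Differential-peak thresholds applied when count
#'   matrices are present (defaults 2 and 0.05).
#' @param p_max Per-dataset enrichment significance threshold for the
#'   intersection (default 0.05).
#' @param hit_alpha Per-window hit-calling tail probability (default 1e-4).
#' @param match_mode,sim_min Cross-dataset matching, see
#'   [intersect_enriched()].
#' @param design_cfg A [design_config()].
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed feeds simulation when `datasets` is a
#'   `SimConfig`-driven study built by the caller).
#' @return Invisibly, a list: `enrichment` (per dataset), `conserved`,
#'   `designs`, `diff_peaks` (per dataset or NULL), `out_dir`.
#' @export
run_pipeline <- function(datasets, library, out_dir,
                         fc_min = 2, fdr_max = 0.05, p_max = 0.05,
                         hit_alpha = 1e-4,
                         match_mode = c("by_id", "by_similarity"),
                         sim_min = 0.80, design_cfg = design_config(),
                         seed = 1L) {
  match_mode <- match.arg(match_mode)
  if (is.character(library)) library <- read_motifs(library, "jaspar")
  library <- unique_motif_ids(library)

  counts <- NULL
  if (inherits(datasets, "SimStudy")) {
    counts <- datasets$counts
    datasets <- datasets$datasets
  }
  datasets <- lapply(datasets, function(d) {
    lapply(d[c("target", "background")], function(x) {
      if (is.character(x)) {
        if (!file.exists(x)) stopf("run_pipeline: missing input path '%s'", x)
        read_peak_fasta(x)
      } else x
    })
  })
  K <- length(datasets)
  if (K < 1) stopf("run_pipeline: no datasets")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs_dir <- file.path(out_dir, "inputs")
  dir.create(inputs_dir, showWarnings = FALSE)
  for (d in seq_len(K)) for (side in c("target", "background"))
    write_peak_fasta(datasets[[d]][[side]],
                     file.path(inputs_dir, sprintf("ds%d_%s.fa", d, side)))
  write_motifs_jaspar(library, file.path(inputs_dir, "library.jaspar"))

  message(sprintf("[promforge] %d dataset(s), %d motifs", K, length(library)))
  diff_peaks <- NULL
  if (!is.null(counts)) {
    diff_peaks <- lapply(seq_len(K), function(d) {
      dp <- select_differential_peaks(counts[[d]], fc_min, fdr_max)
      utils::write.table(dp, file.path(out_dir, sprintf("ds%d_diffpeaks.tsv", d)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dp
    })
  }

  enrichment <- lapply(seq_len(K), function(d) {
    message(sprintf("[promforge] enrichment: dataset %d", d))
    res <- motif_enrichment(library, datasets[[d]]$target,
                            datasets[[d]]$background, hit_alpha = hit_alpha)
    write_enrichment_tsv(res, file.path(out_dir, sprintf("ds%d_enrichment.tsv", d)))
    res
  })

  conserved <- if (K >= 2) {
    cs <- intersect_enriched(enrichment, libraries = rep(list(library), K),
                             p_max = p_max, match_mode = match_mode,
                             sim_min = sim_min)
    write_conserved_tsv(cs, file.path(out_dir, "conserved_motifs.tsv"))
    cs
  } else {
    e1 <- enrichment[[1]]
    e1[e1$p_value < p_max, , drop = FALSE]
  }

  ids <- if (K >= 2) conserved$canonical_id else conserved$motif_id
  message(sprintf("[promforge] designing %d promoter(s)", length(ids)))
  designs <- lapply(ids, function(id)
    build_promoter(library[[id]], library, design_cfg))
  names(designs) <- ids
  if (length(designs)) {
    write_designs_tsv(designs, file.path(out_dir, "designs.tsv"))
    for (d in designs)
      write_genbank(d, file.path(out_dir, sprintf(
        "design_%s.gb", gsub("[^A-Za-z0-9_.-]", "_", d$motif_id))))
  }

  files <- sort(list.files(inputs_dir, full.names = TRUE))
  manifest <- list(
    package = "promforge",
    version = as.character(utils::packageVersion("promforge")),
    seed = seed,
    config = list(fc_min = fc_min, fdr_max = fdr_max, p_max = p_max,
                  hit_alpha = hit_alpha, match_mode = match_mode,
                  sim_min = sim_min,
                  target_site_bp = design_cfg$target_site_bp,
                  spacer_len = design_cfg$spacer_len,
                  core_promoter_name = design_cfg$core_promoter_name),
    input_checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                              basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(enrichment = enrichment, conserved = conserved,
                 designs = designs, diff_peaks = diff_peaks,
                 out_dir = out_dir))
}

#' Read a pipeline configuration file
#'
#' YAML-style `key: value` configuration; recognized keys mirror
#' [run_pipeline()] arguments (`fc_min`, `fdr_max`, `p_max`, `hit_alpha`,
#' `match_mode`, `sim_min`, `target_site_bp`, `spacer_len`,
#' `core_promoter_fasta`, `seed`) plus input paths. Unknown keys are kept
#' so callers can pass tool-specific settings through.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("read_run_config: no such file '%s'", path)
  yaml::read_yaml(path)
}
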