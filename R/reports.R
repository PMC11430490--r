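#' Run configuration for the report pipelines
#'
#' Collects the tunable parameters of [characterize_genome()] and the
#' `mitoprofile` command-line interface, applying defaults for anything not
#' supplied. The configuration is echoed into every output directory as
#' `config.json` so a run can be reproduced from its outputs alone.
#'
#' @param ... Named overrides of the defaults: `motifs`, `overlapping`,
#'   `window`, `step`, `band`, `match`, `mismatch`, `gap_open`,
#'   `gap_extend`, `anchor`, `seed`, `at_target`, `n_substitutions`,
#'   `n_insertions`, `n_deletions`, `max_indel`, `min_spacing`.
#' @return List of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    motifs = c("TATAA", "AATAAT"), overlapping = TRUE,
    window = 500L, step = 250L,
    band = 200L, match = 1, mismatch = -1, gap_open = -4, gap_extend = -1,
    anchor = NULL, seed = 1L, at_target = 0.614,
    n_substitutions = 30L, n_insertions = 4L, n_deletions = 9L,
    max_indel = 3L, min_spacing = 50L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) {
    stop("unknown config option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  structure(cfg, class = "RunConfig")
}

write_config <- function(cfg, dir) {
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Characterize a mitogenome: full per-genome report bundle
#'
#' Runs the per-genome analyses — inventory, spacer/overlap table,
#' composition and skew profiles, sliding-window skew, codon usage with
#' RSCU, amino-acid frequencies, terminal-codon classes, and the
#' control-region report — and writes TSV reports with JSON twins into
#' `out_dir`. Outputs are deterministic for fixed inputs and configuration.
#'
#' @param g A [circular_sequence()].
#' @param ann A [mitogenome_annotation()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param config A [run_config()].
#' @return List of class `CharacterizationReport` with components
#'   `inventory`, `spacers`, `profiles`, `window_skew`, `codon_usage`,
#'   `terminal_codons`, `control_region`.
#' @export
characterize_genome <- function(g, ann, out_dir = NULL,
                                config = run_config()) {
  stopifnot(inherits(g, "CircularSequence"),
            inherits(ann, "MitogenomeAnnotation"))
  res <- list(
    inventory = summarize_inventory(ann),
    spacers = spacer_overlap_table(ann),
    profiles = region_profiles(g, ann),
    window_skew = sliding_window_skew(g, min(config$window, g$length),
                                      config$step),
    codon_usage = codon_usage_table(ann, g),
    terminal_codons = classify_terminal_codons(ann, g),
    control_region = control_region_report(
      g, ann, motifs = config$motifs, overlapping = config$overlapping)
  )
  class(res) <- "CharacterizationReport"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, out_dir)
    write_layout_reports(res$spacers, res$inventory, out_dir)
    write_composition_reports(res$profiles, out_dir)
    write_codon_reports(res$codon_usage, out_dir)
    write_control_region_reports(res$control_region, out_dir)
    write.table(res$terminal_codons,
                file.path(out_dir, "terminal_codons.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$window_skew, file.path(out_dir, "window_skew.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' @export
print.CharacterizationReport <- function(x, ...) {
  print(x$inventory)
  print(x$control_region)
  invisible(x)
}

#' Compare two mitogenome files and write reports
#'
#' File-level wrapper around [compare_genomes()]: reads the reference
#' FASTA + feature table and the query FASTA, runs the comparison, and
#' writes variant/consequence TSVs, a minimal VCF and a JSON summary.
#'
#' @param ref_fasta,ref_features,query_fasta Input paths.
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param config A [run_config()] (alignment scores, band, anchor).
#' @return The [compare_genomes()] result.
#' @export
compare_files <- function(ref_fasta, ref_features, query_fasta,
                          out_dir = NULL, config = run_config()) {
  ref <- read_fasta(ref_fasta)
  ann <- read_feature_table(ref_features, ref$length)
  query <- read_fasta(query_fasta)
  cmp <- compare_genomes(ref, ann, query, anchor = config$anchor,
                         band = config$band, match = config$match,
                         mismatch = config$mismatch,
                         gap_open = config$gap_open,
                         gap_extend = config$gap_extend)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, out_dir)
    write_variant_reports(cmp, ref, out_dir)
    jsonlite::write_json(
      list(n_variants = cmp$summary$n_variants,
           n_substitutions = cmp$summary$n_substitutions,
           n_insertions = cmp$summary$n_insertions,
           n_deletions = cmp$summary$n_deletions,
           n_aa_changing = cmp$summary$n_aa_changing),
      file.path(out_dir, "diff_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cmp
}

#' Simulate a genome (pair) and write the bundle
#'
#' Generates a synthetic annotated mitogenome and, when the configured
#' mutation counts are positive, a mutated partner with its truth set.
#'
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param config A [run_config()] (`seed`, `at_target`, mutation counts).
#' @param layout A [layout_spec()].
#' @return List with `genome`, `annotation`, and (if mutations were
#'   requested) `mutated` and `truth`.
#' @export
simulate_files <- function(out_dir = NULL, config = run_config(),
                           layout = default_layout()) {
  sim <- generate_genome(layout, at_target = config$at_target,
                         seed = config$seed)
  out <- list(genome = sim$genome, annotation = sim$annotation)
  n_mut <- config$n_substitutions + config$n_insertions + config$n_deletions
  if (n_mut > 0L) {
    plan <- mutation_plan(config$n_substitutions, config$n_insertions,
                          config$n_deletions, config$max_indel,
                          config$min_spacing, seed = config$seed + 1L)
    mut <- mutate_genome(sim$genome, sim$annotation, plan)
    out$mutated <- mut$genome
    out$truth <- mut$truth
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, out_dir)
    write_simulation(sim, out_dir, truth = out$truth)
    if (!is.null(out$mutated)) {
      write_fasta(out$mutated, file.path(out_dir, "mutated.fasta"))
    }
  }
  out
}
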