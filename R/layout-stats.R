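#' Signed intergenic gap between two consecutive features
#'
#' The gap is `downstream$start - upstream$stop - 1`: the number of
#' unannotated bases between the two features. Negative values are overlaps
#' (the features share `-gap` bases), the usual situation for `atp8`/`atp6`
#' in vertebrate mitogenomes. The raw difference is normalized into
#' `(-L/2, L/2]`, so pairs spanning the linearization origin (in either
#' direction) get their true circular gap; this is unambiguous for real
#' annotations, where overlaps are tens of bases, not half a genome.
#'
#' @param upstream,downstream One-row feature `data.frame`s, `downstream`
#'   being the next feature in genome order.
#' @param L Genome length in bp.
#' @return Signed gap in bp.
#' @examples
#' a <- gene_feature("atp8", "PCG", 7929, 8111, "+")
#' b <- gene_feature("atp6", "PCG", 8090, 8764, "+")
#' intergenic_gap(a, b, 16541)  # -22
#' @export
intergenic_gap <- function(upstream, downstream, L) {
  gap <- (downstream$start - upstream$stop - 1L) %% L
  if (gap > L / 2) gap <- gap - L
  as.integer(gap)
}

#' Intergenic spacer / overlap table
#'
#' One record per consecutive feature pair in genome order, including the
#' pair that closes the circle (last feature back to the first). Features
#' must be sorted by start (as [mitogenome_annotation()] guarantees);
#' features entirely contained in another are still paired by start order,
#' with a warning.
#'
#' @param ann A [mitogenome_annotation()] with at least two features.
#' @return A `data.frame` of class `SpacerTable` with columns
#'   `upstream_name`, `downstream_name`, `gap` (signed bp; negative =
#'   overlap), carrying attributes `longest_gap`, `n_gaps` (count of strictly
#'   positive gaps) and `n_overlaps`.
#' @export
spacer_overlap_table <- function(ann) {
  stopifnot(inherits(ann, "MitogenomeAnnotation"))
  f <- ann$features
  n <- nrow(f)
  if (n < 2L) stop("spacer accounting needs at least 2 features")
  L <- ann$genome_length
  ## containment check on non-wrapping spans: degenerate but must not crash
  nonwrap <- which(f$stop >= f$start)
  for (i in nonwrap) {
    inside <- any(f$start[nonwrap] <= f$start[i] &
                    f$stop[nonwrap] >= f$stop[i] &
                    nonwrap != i)
    if (inside) {
      warning(sprintf("feature '%s' is entirely contained in another feature; %s",
                      f$name[i], "pairing by start order anyway"))
    }
  }
  up <- seq_len(n)
  down <- c(seq_len(n)[-1L], 1L)
  gap <- integer(n)
  for (i in seq_len(n)) {
    gap[i] <- intergenic_gap(f[up[i], ], f[down[i], ], L)
  }
  out <- data.frame(upstream_name = f$name[up],
                    downstream_name = f$name[down],
                    gap = gap, stringsAsFactors = FALSE)
  class(out) <- c("SpacerTable", "data.frame")
  attr(out, "longest_gap") <- if (any(gap > 0L)) max(gap) else 0L
  attr(out, "n_gaps") <- sum(gap > 0L)
  attr(out, "n_overlaps") <- sum(gap < 0L)
  out
}

#' @export
print.SpacerTable <- function(x, ...) {
  cat(sprintf(
    "SpacerTable: %d pairs | %d spacers (longest %d bp) | %d overlaps\n",
    nrow(x), attr(x, "n_gaps"), attr(x, "longest_gap"), attr(x, "n_overlaps")
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Gene inventory summary
#'
#' Counts features by class and summarizes lengths: total protein-coding
#' span in bp and as a percentage of the genome (rounded to 2 decimals, the
#' precision used in mitogenome descriptions), and the tRNA size range.
#'
#' @param ann A [mitogenome_annotation()].
#' @return List of class `InventorySummary`: `n_total`, `n_pcg`, `n_trna`,
#'   `n_rrna`, `has_control_region`, `pcg_total_bp`, `pcg_fraction`,
#'   `trna_min_bp`, `trna_max_bp`, and `lengths_by_class` (named list of
#'   per-feature length vectors).
#' @export
summarize_inventory <- function(ann) {
  stopifnot(inherits(ann, "MitogenomeAnnotation"))
  f <- ann$features
  L <- ann$genome_length
  len <- vapply(seq_len(nrow(f)),
                function(i) feature_length(f[i, ], L), integer(1))
  by_class <- split(setNames(len, f$name), f$class)
  n_of <- function(cls) sum(f$class == cls)
  pcg_total <- sum(len[f$class == "PCG"])
  trna_len <- len[f$class == "tRNA"]
  structure(list(
    n_total = nrow(f),
    n_pcg = n_of("PCG"),
    n_trna = n_of("tRNA"),
    n_rrna = n_of("rRNA"),
    has_control_region = n_of("control_region") > 0L,
    pcg_total_bp = pcg_total,
    pcg_fraction = round(100 * pcg_total / L, 2L),
    trna_min_bp = if (length(trna_len)) min(trna_len) else NA_integer_,
    trna_max_bp = if (length(trna_len)) max(trna_len) else NA_integer_,
    lengths_by_class = by_class,
    genome_length = L
  ), class = "InventorySummary")
}

#' @export
print.InventorySummary <- function(x, ...) {
  cat(sprintf("InventorySummary: %d features on %d bp\n", x$n_total,
              x$genome_length))
  cat(sprintf("  PCG %d (%d bp, %.2f%% of genome)  tRNA %d (%s-%s bp)  rRNA %d  CR %s\n",
              x$n_pcg, x$pcg_total_bp, x$pcg_fraction, x$n_trna,
              x$trna_min_bp, x$trna_max_bp, x$n_rrna,
              if (x$has_control_region) "yes" else "no"))
  invisible(x)
}

#' Write spacer table and inventory reports
#'
#' TSV for the spacer table; JSON twin for the inventory summary.
#'
#' @param spacers A [spacer_overlap_table()] result.
#' @param inventory A [summarize_inventory()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_layout_reports <- function(spacers, inventory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "spacer_table.tsv")
  write.table(as.data.frame(spacers), p1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p2 <- file.path(dir, "inventory.json")
  inv <- inventory[setdiff(names(inventory), "lengths_by_class")]
  inv$lengths_by_class <- lapply(inventory$lengths_by_class, as.list)
  jsonlite::write_json(inv, p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2))
}
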