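#' Codon counts of one or more coding sequences
#'
#' Counts codons in frame 0. Codons containing `N` are skipped and reported
#' via the `n_ambiguous` attribute; trailing incomplete codons are ignored.
#'
#' @param seqs Character vector of coding-strand DNA sequences.
#' @return Named integer vector over the 64 codons (attribute
#'   `n_ambiguous` gives the count of skipped N-containing codons).
#' @export
codon_counts <- function(seqs) {
  all_codons <- all_codon_names()
  counts <- setNames(integer(64L), all_codons)
  n_amb <- 0L
  for (s in seqs) {
    cods <- split_codons(toupper(s))$codons
    idx <- match(cods, all_codons)
    n_amb <- n_amb + sum(is.na(idx))
    tab <- tabulate(idx[!is.na(idx)], nbins = 64L)
    counts <- counts + tab
  }
  attr(counts, "n_ambiguous") <- n_amb
  counts
}

all_codon_names <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' Relative synonymous codon usage
#'
#' For a codon `c` in a synonymous family of size `k` with family total
#' `n_fam`, `RSCU(c) = count(c) * k / n_fam`: the observed count divided by
#' the count expected if all synonyms were used equally. Values sum to `k`
#' within each family; a family with zero total gets all-zero RSCU. Stop
#' codons are excluded (they are not synonymous codon choices for an amino
#' acid).
#'
#' @param counts Named integer vector of codon counts (as from
#'   [codon_counts()]; stop-codon entries are ignored).
#' @param code A [mito_genetic_code()].
#' @return Named numeric vector of RSCU values over the sense codons.
#' @examples
#' cc <- codon_counts("ATGATGATAATA")
#' rscu(cc)[c("ATG", "ATA")]  # both 1.0
#' @export
rscu <- function(counts, code = mito_genetic_code()) {
  stopifnot(inherits(code, "GeneticCode"))
  if (any(counts < 0L)) stop("negative codon count")
  sense <- setdiff(names(code$codon_to_aa), code$stop_codons)
  counts <- counts[sense]
  counts[is.na(counts)] <- 0L
  names(counts) <- sense
  aa <- code$codon_to_aa[sense]
  out <- setNames(numeric(length(sense)), sense)
  for (a in unique(aa)) {
    fam <- sense[aa == a]
    k <- length(fam)
    tot <- sum(counts[fam])
    out[fam] <- if (tot > 0L) counts[fam] * k / tot else 0
  }
  out
}

#' Codon usage table for the protein-coding genes of a genome
#'
#' Extracts every PCG in genome order on its coding strand, counts codons,
#' and computes RSCU and amino-acid frequencies (percent of all translated
#' residues, stop codons excluded).
#'
#' @param ann A [mitogenome_annotation()] with PCG features.
#' @param g A [circular_sequence()].
#' @param code A [mito_genetic_code()].
#' @return List of class `CodonUsageTable`: `counts` (64 codons), `rscu`
#'   (sense codons), `aa_freq` (named percentages summing to 100), and
#'   `table` (a `data.frame` with columns `codon`, `aa`, `count`, `rscu`
#'   ordered by amino acid).
#' @export
codon_usage_table <- function(ann, g, code = mito_genetic_code()) {
  seqs <- pcg_sequences(ann, g)
  counts <- codon_counts(seqs)
  r <- rscu(counts, code)
  freq <- aa_freq_from_counts(counts, code)
  sense <- names(r)
  tab <- data.frame(codon = sense, aa = unname(code$codon_to_aa[sense]),
                    count = unname(counts[sense]), rscu = unname(r),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aa, tab$codon), ]
  rownames(tab) <- NULL
  structure(list(counts = counts, rscu = r, aa_freq = freq, table = tab),
            class = "CodonUsageTable")
}

#' @export
print.CodonUsageTable <- function(x, ...) {
  cat(sprintf("CodonUsageTable: %d codons counted over %d sense codons\n",
              sum(x$counts), sum(x$counts[names(x$rscu)] > 0)))
  print(head(x$table, 10L))
  cat("  ...\n")
  invisible(x)
}

pcg_sequences <- function(ann, g) {
  f <- ann$features[ann$features$class == "PCG", , drop = FALSE]
  if (!nrow(f)) stop("annotation contains no PCG features")
  vapply(seq_len(nrow(f)), function(i) extract_feature_sequence(g, f[i, ]),
         character(1))
}

aa_freq_from_counts <- function(counts, code) {
  sense <- setdiff(names(code$codon_to_aa), code$stop_codons)
  cnt <- counts[sense]
  cnt[is.na(cnt)] <- 0L
  aa <- code$codon_to_aa[sense]
  per_aa <- tapply(cnt, aa, sum)
  tot <- sum(per_aa)
  if (tot == 0L) stop("no sense codons counted")
  100 * per_aa[order(names(per_aa))] / tot
}

#' Amino-acid frequencies of the protein-coding genes
#'
#' Percentages over all translated residues of the PCGs, stop codons
#' excluded; sums to 100.
#'
#' @inheritParams codon_usage_table
#' @return Named numeric vector of percentages (one per amino acid observed
#'   in the code).
#' @export
aa_frequencies <- function(ann, g, code = mito_genetic_code()) {
  counts <- codon_counts(pcg_sequences(ann, g))
  aa_freq_from_counts(counts, code)
}

#' Write codon usage reports
#'
#' TSV RSCU table (codon, amino acid, count, RSCU, ordered by amino acid)
#' and a JSON amino-acid frequency report.
#'
#' @param cut A [codon_usage_table()] result.
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_codon_reports <- function(cut, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "rscu.tsv")
  tab <- cut$table
  tab$rscu <- round(tab$rscu, 5L)
  write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "aa_frequencies.json")
  jsonlite::write_json(as.list(round(cut$aa_freq, 5L)), p2,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2))
}
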