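#' Vertebrate mitochondrial genetic code
#'
#' NCBI translation table 2, in which `TGA` encodes tryptophan, `ATA`
#' encodes methionine, and `AGA`/`AGG` are stop codons. The codon-to-amino
#' acid map is taken from Biostrings' genetic code registry; start-codon
#' classification follows vertebrate mitochondrial usage: any `ATN` codon is
#' a canonical initiator, while `TTG` and `GTG` are recognized alternatives.
#'
#' @param code_id NCBI genetic code id (default `2`; any id known to
#'   [Biostrings::getGeneticCode()] is accepted).
#' @return Object of class `GeneticCode`: list with `code_id`,
#'   `codon_to_aa` (named character of 64 codons), `stop_codons`,
#'   `canonical_starts`, `alternative_starts`.
#' @export
mito_genetic_code <- function(code_id = 2L) {
  map <- Biostrings::getGeneticCode(as.character(code_id))
  structure(list(
    code_id = as.integer(code_id),
    codon_to_aa = map,
    stop_codons = names(map)[map == "*"],
    canonical_starts = c("ATA", "ATC", "ATG", "ATT"),
    alternative_starts = c("TTG", "GTG")
  ), class = "GeneticCode")
}

#' @export
print.GeneticCode <- function(x, ...) {
  cat(sprintf("GeneticCode: NCBI table %d (stops: %s)\n", x$code_id,
              paste(x$stop_codons, collapse = ", ")))
  invisible(x)
}

## Split a DNA string into complete codons (frame 0) plus remainder.
split_codons <- function(seq) {
  n <- nchar(seq)
  n_codons <- n %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  list(codons = substring(seq, starts, starts + 2L),
       remainder = if (n %% 3L) substr(seq, 3L * n_codons + 1L, n) else "")
}

#' Translate a coding sequence
#'
#' Translation starts at frame 0 and emits one letter per complete codon
#' (`*` for stops). In vertebrate mitochondria many genes end on a 1-2 base
#' remainder (`T` or `TA`) completed to `TAA` by polyadenylation, so
#' trailing bases are reported rather than rejected. Codons containing `N`
#' translate as `X`.
#'
#' @param seq DNA string, length >= 3.
#' @param code A [mito_genetic_code()].
#' @return List of class `Translation`: `protein` (string, stops as `*`),
#'   `remainder` (trailing 1-2 bases or `""`), `internal_stops` (codon
#'   indices of stop codons before the final codon).
#' @examples
#' translate_cds("ATGTGA", mito_genetic_code())$protein  # "MW"
#' @export
translate_cds <- function(seq, code = mito_genetic_code()) {
  stopifnot(inherits(code, "GeneticCode"))
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("coding sequence shorter than one codon")
  parts <- split_codons(seq)
  aa <- unname(code$codon_to_aa[parts$codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  stops <- which(aa == "*")
  structure(list(
    protein = paste(aa, collapse = ""),
    remainder = parts$remainder,
    internal_stops = stops[stops < length(aa)]
  ), class = "Translation")
}

#' Classify start and stop codons of protein-coding genes
#'
#' For every PCG in the annotation, extracts the coding-strand sequence and
#' classifies its terminal codons. Start classes: `canonical-ATN` (any
#' `ATN`), `alternative` (`TTG`/`GTG`), `invalid`. Stop classes: `complete`
#' (a stop codon of the code), `incomplete` (a trailing `T` or `TA`
#' remainder, completed by polyadenylation in vivo), `invalid`.
#'
#' @param ann A [mitogenome_annotation()] containing PCG features.
#' @param g A [circular_sequence()].
#' @param code A [mito_genetic_code()].
#' @return `data.frame` with columns `gene`, `start_codon`, `start_class`,
#'   `stop_codon`, `stop_class`, `n_internal_stops`.
#' @export
classify_terminal_codons <- function(ann, g, code = mito_genetic_code()) {
  stopifnot(inherits(ann, "MitogenomeAnnotation"),
            inherits(g, "CircularSequence"))
  f <- ann$features[ann$features$class == "PCG", , drop = FALSE]
  if (!nrow(f)) stop("annotation contains no PCG features")
  rows <- lapply(seq_len(nrow(f)), function(i) {
    s <- extract_feature_sequence(g, f[i, ])
    if (nchar(s) < 6L) {
      stop(sprintf("PCG '%s' is shorter than 6 bp", f$name[i]))
    }
    start_codon <- substr(s, 1L, 3L)
    start_class <- if (grepl("^AT[ACGT]$", start_codon)) {
      "canonical-ATN"
    } else if (start_codon %in% code$alternative_starts) {
      "alternative"
    } else "invalid"
    tr <- translate_cds(s, code)
    if (tr$remainder == "") {
      stop_codon <- substr(s, nchar(s) - 2L, nchar(s))
      stop_class <- if (stop_codon %in% code$stop_codons) "complete" else "invalid"
    } else {
      stop_codon <- tr$remainder
      stop_class <- if (tr$remainder %in% c("T", "TA")) "incomplete" else "invalid"
    }
    data.frame(gene = f$name[i], start_codon = start_codon,
               start_class = start_class, stop_codon = stop_codon,
               stop_class = stop_class,
               n_internal_stops = length(tr$internal_stops),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
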