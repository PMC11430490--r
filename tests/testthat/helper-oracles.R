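# Independent oracles and fixture builders shared across the suite.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# character-by-character composition tally, independent of base_counts()
oracle_tally <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  vapply(c(A = "A", C = "C", G = "G", T = "T", N = "N"),
         function(b) sum(chars == b), integer(1))
}

oracle_skews <- function(seq) {
  cnt <- oracle_tally(seq)
  c(at_skew = (cnt[["A"]] - cnt[["T"]]) / (cnt[["A"]] + cnt[["T"]]),
    gc_skew = (cnt[["G"]] - cnt[["C"]]) / (cnt[["G"]] + cnt[["C"]]),
    at_content = (cnt[["A"]] + cnt[["T"]]) /
      (cnt[["A"]] + cnt[["C"]] + cnt[["G"]] + cnt[["T"]]))
}

# position-by-position motif scan
oracle_motif_count <- function(seq, motif, overlapping = TRUE) {
  n <- nchar(seq); k <- nchar(motif)
  pos <- integer(0)
  i <- 1L
  while (i <= n - k + 1L) {
    if (substr(seq, i, i + k - 1L) == motif) {
      pos <- c(pos, i)
      i <- i + (if (overlapping) 1L else k)
    } else {
      i <- i + 1L
    }
  }
  pos
}

# enumerate maximal primitive tandem arrays by direct substring comparison
oracle_tandem_repeats <- function(seq, min_unit, max_unit, min_copies = 2L) {
  n <- nchar(seq)
  sub <- function(i, j) substr(seq, i, j)
  primitive <- function(x) {
    k <- nchar(x)
    if (k == 1L) return(TRUE)
    for (p in seq_len(k %/% 2L)) {
      if (k %% p == 0L &&
          x == paste(rep(substr(x, 1L, p), k %/% p), collapse = "")) {
        return(FALSE)
      }
    }
    TRUE
  }
  rows <- list()
  for (u in min_unit:max_unit) {
    for (start in seq_len(n - 2L * u + 1L)) {
      unit <- sub(start, start + u - 1L)
      if (!primitive(unit)) next
      # leftmost phase of the periodic stretch only
      if (start > 1L && sub(start - 1L, start - 1L) ==
          sub(start + u - 1L, start + u - 1L)) next
      copies <- 1L
      while (start + (copies + 1L) * u - 1L <= n &&
             sub(start + copies * u, start + (copies + 1L) * u - 1L) == unit) {
        copies <- copies + 1L
      }
      if (copies >= min_copies) {
        rows[[length(rows) + 1L]] <- data.frame(
          unit = unit, unit_length = u, copies = copies, start = start,
          total_span = u * copies, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(unit = character(0), unit_length = integer(0),
                      copies = integer(0), start = integer(0),
                      total_span = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  # same-unit arrays are reported disjoint, trimmed greedily from the left
  keep <- rep(TRUE, nrow(out))
  last_end <- list()
  for (j in seq_len(nrow(out))) {
    u <- out$unit[j]
    le <- last_end[[u]]
    if (!is.null(le) && out$start[j] <= le) {
      shift <- ceiling((le + 1L - out$start[j]) / out$unit_length[j])
      out$start[j] <- out$start[j] + shift * out$unit_length[j]
      out$copies[j] <- out$copies[j] - shift
      out$total_span[j] <- out$unit_length[j] * out$copies[j]
      if (out$copies[j] < min_copies) {
        keep[j] <- FALSE
        next
      }
    }
    last_end[[u]] <- out$start[j] + out$total_span[j] - 1L
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Biostrings global aligner as an independent scoring oracle
# (same gap convention: a k-long gap costs open + k * extend)
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 4, gap_extend = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  Biostrings::score(pa)
}

# small random layouts for conservation properties
random_layout <- function(n_features = 6L) {
  classes <- sample(c("PCG", "tRNA", "rRNA"), n_features, replace = TRUE)
  classes[n_features] <- "control_region"
  len <- sample(60:600, n_features, replace = TRUE)
  len[classes == "PCG"] <- (len[classes == "PCG"] %/% 3L) * 3L
  gap <- sample(c(0L, 0L, 1L, 3L, 15L, 40L), n_features, replace = TRUE)
  over <- sample(seq_len(n_features - 1L), 1L)
  gap[over] <- -min(10L, len[over] - 1L, len[over + 1L] - 1L)
  layout_spec(data.frame(
    name = paste0("f", seq_len(n_features)), class = classes,
    length = len,
    strand = sample(c("+", "-"), n_features, replace = TRUE),
    gap_to_next = gap, stringsAsFactors = FALSE))
}

table1_lengths <- c(
  trnF = 71, rrnS = 949, trnV = 66, rrnL = 1565, trnL2 = 75, nad1 = 951,
  trnI = 70, trnQ = 72, trnM = 68, nad2 = 1038, trnW = 67, trnA = 69,
  trnN = 73, trnC = 66, trnY = 65, cox1 = 1542, trnS2 = 69, trnD = 69,
  cox2 = 660, trnK = 68, atp8 = 183, atp6 = 675, cox3 = 783, trnG = 67,
  nad3 = 345, trnR = 65, nad4l = 294, nad4 = 1368, trnH = 69, trnS1 = 59,
  trnL1 = 71, nad5 = 1800, nad6 = 519, trnE = 69, cob = 1134, trnT = 65,
  trnP = 67)

# printed inter-feature gap column, keyed by the upstream gene
table1_gaps <- c(
  trnF = 0, rrnS = 0, trnV = -2, rrnL = 0, trnL2 = 2, nad1 = 4, trnI = -3,
  trnQ = 0, trnM = 0, nad2 = 4, trnW = 7, trnA = 1, trnN = 32, trnC = 0,
  trnY = 1, cox1 = 0, trnS2 = 3, trnD = 1, cox2 = 68, trnK = 1, atp8 = -22,
  atp6 = 5, cox3 = 1, trnG = 0, nad3 = 1, trnR = 0, nad4l = -4, nad4 = 10,
  trnH = 0, trnS1 = 0, trnL1 = 3, nad5 = 15, nad6 = 0, trnE = 4, cob = 7,
  trnT = 2)

douc_annotation <- function() {
  read_feature_table(
    system.file("extdata", "douc_features.tsv", package = "mitoprofile"),
    16541)
}

# tiny annotated toy genome with one PCG and one control region
toy_pcg_genome <- function(cds = "ATGGCTGCATAA", strand = "+") {
  cr <- "ACGTACGTACGTACGT"
  residues <- if (strand == "+") paste0(cds, cr) else
    paste0(revcomp(cds), cr)
  g <- circular_sequence(residues, id = "toy")
  ann <- mitogenome_annotation(rbind(
    gene_feature("pcg1", "PCG", 1, nchar(cds), strand),
    gene_feature("cr", "control_region", nchar(cds) + 1, g$length, "+")
  ), g$length)
  list(genome = g, annotation = ann)
}

default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        generate_genome(default_layout(), at_target = 0.614, seed = 42))
    }
    cache
  }
})
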