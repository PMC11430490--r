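#' Count occurrences of a motif
#'
#' Overlapping mode (the default) counts every start position at which the
#' motif matches; non-overlapping mode scans left to right greedily,
#' restarting after each match.
#'
#' @param seq DNA string to scan.
#' @param motif Non-empty DNA motif without ambiguity codes.
#' @param overlapping Count overlapping occurrences?
#' @return List with `count` and `positions` (1-based start positions).
#' @examples
#' count_motif("AAAA", "AA")$count                        # 3
#' count_motif("AAAA", "AA", overlapping = FALSE)$count   # 2
#' @export
count_motif <- function(seq, motif, overlapping = TRUE) {
  motif <- toupper(motif)
  if (nchar(motif) < 1L) stop("motif must be non-empty")
  if (grepl("[^ACGT]", motif)) stop("motif may only contain A, C, G, T")
  seq <- toupper(seq)
  if (overlapping) {
    hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  } else {
    hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  }
  pos <- if (hits[1L] == -1L) integer(0) else as.integer(hits)
  list(count = length(pos), positions = pos)
}

#' Find maximal exact tandem repeats
#'
#' Scans for arrays of two or more exact adjacent copies of a repeat unit.
#' Only maximal, primitive arrays are reported: the array cannot be extended
#' by a full unit on either side, the unit is not itself periodic (so a
#' poly-A run is reported once with unit `A`, not again with unit `AA`), and
#' for each periodic stretch the leftmost phase of the unit is used. Arrays
#' of the same unit are reported disjoint: when two maximal stretches of a
#' unit meet with a partial overlap, the later one is trimmed forward by
#' whole units (and dropped if fewer than `min_copies` remain). The search
#' is the naive exact algorithm, O(n * max_unit), which is ample for
#' control-region-sized (~1 kb) input.
#'
#' @param seq DNA string.
#' @param min_unit,max_unit Unit length range in bp.
#' @param min_copies Minimum number of exact copies (>= 2).
#' @return `data.frame` with columns `unit`, `unit_length`, `copies`,
#'   `start`, `total_span` (`= unit_length * copies`), sorted by `start`.
#' @examples
#' find_exact_tandem_repeats("ACACAC", 1, 3)  # unit "AC", 3 copies
#' @export
find_exact_tandem_repeats <- function(seq, min_unit = 1L, max_unit = 6L,
                                      min_copies = 2L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  min_unit <- as.integer(min_unit); max_unit <- as.integer(max_unit)
  if (min_unit < 1L || max_unit < min_unit || max_unit > n %/% 2L) {
    stop("need 1 <= min_unit <= max_unit <= length(seq)/2")
  }
  if (min_copies < 2L) stop("min_copies must be >= 2")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (u in min_unit:max_unit) {
    ## positions i where seq[i] == seq[i + u]
    m <- chars[seq_len(n - u)] == chars[(u + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_len <- r$lengths[k]
      region_len <- run_len + u
      copies <- region_len %/% u
      if (copies < min_copies) next
      start <- starts[k]
      unit <- substr(seq, start, start + u - 1L)
      if (is_periodic(unit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit = unit, unit_length = u, copies = copies, start = start,
        total_span = u * copies, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(unit = character(0), unit_length = integer(0),
                      copies = integer(0), start = integer(0),
                      total_span = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- disjoint_per_unit(out[order(out$start, out$unit_length), ,
                               drop = FALSE], min_copies)
  rownames(out) <- NULL
  out
}

## Greedy left-to-right: trim a same-unit array that overlaps the previous
## one forward by whole units; drop it if too few copies remain.
disjoint_per_unit <- function(tab, min_copies) {
  keep <- rep(TRUE, nrow(tab))
  last_end <- list()
  for (j in seq_len(nrow(tab))) {
    u <- tab$unit[j]
    le <- last_end[[u]]
    if (!is.null(le) && tab$start[j] <= le) {
      shift <- ceiling((le + 1L - tab$start[j]) / tab$unit_length[j])
      tab$start[j] <- tab$start[j] + shift * tab$unit_length[j]
      tab$copies[j] <- tab$copies[j] - shift
      tab$total_span[j] <- tab$unit_length[j] * tab$copies[j]
      if (tab$copies[j] < min_copies) {
        keep[j] <- FALSE
        next
      }
    }
    last_end[[u]] <- tab$start[j] + tab$total_span[j] - 1L
  }
  tab <- tab[keep, , drop = FALSE]
  tab[order(tab$start, tab$unit_length), , drop = FALSE]
}

## TRUE if x equals a repetition of one of its proper prefixes.
is_periodic <- function(x) {
  n <- nchar(x)
  if (n == 1L) return(FALSE)
  for (p in seq_len(n %/% 2L)) {
    if (n %% p == 0L &&
        x == paste(rep(substr(x, 1L, p), n %/% p), collapse = "")) {
      return(TRUE)
    }
  }
  FALSE
}

#' Control-region report
#'
#' Extracts the control region (handling the usual origin-spanning case as a
#' single wrapped feature), and reports its length, composition/skew
#' profile, motif occurrence counts and exact tandem repeats. All positions
#' are control-region-local (1..CR length).
#'
#' @param g A [circular_sequence()].
#' @param ann A [mitogenome_annotation()] with a `control_region` feature.
#' @param motifs Character vector of motifs to count. The defaults are the
#'   short A+T-rich signals commonly scanned for in primate control
#'   regions.
#' @param overlapping Passed to [count_motif()].
#' @param max_unit,min_copies Passed to [find_exact_tandem_repeats()].
#' @return List of class `ControlRegionReport`: `length`, `profile`,
#'   `motifs` (named list of [count_motif()] results), `tandem_repeats`.
#' @export
control_region_report <- function(g, ann, motifs = c("TATAA", "AATAAT"),
                                  overlapping = TRUE, max_unit = 6L,
                                  min_copies = 2L) {
  stopifnot(inherits(g, "CircularSequence"),
            inherits(ann, "MitogenomeAnnotation"))
  f <- ann$features[ann$features$class == "control_region", , drop = FALSE]
  if (!nrow(f)) stop("annotation has no control_region feature")
  cr <- extract_feature_sequence(g, f[1L, ])
  hits <- lapply(motifs, function(m) count_motif(cr, m, overlapping))
  names(hits) <- motifs
  structure(list(
    length = nchar(cr),
    profile = skew_profile(cr, "control_region"),
    motifs = hits,
    tandem_repeats = find_exact_tandem_repeats(
      cr, 1L, min(max_unit, nchar(cr) %/% 2L), min_copies),
    sequence = cr
  ), class = "ControlRegionReport")
}

#' @export
print.ControlRegionReport <- function(x, ...) {
  cat(sprintf("ControlRegionReport: %d bp\n", x$length))
  for (m in names(x$motifs)) {
    cat(sprintf("  motif %s: %d hit(s)\n", m, x$motifs[[m]]$count))
  }
  cat(sprintf("  tandem repeats: %d array(s)\n", nrow(x$tandem_repeats)))
  invisible(x)
}

#' Write control-region reports
#'
#' TSV motif report and TSV tandem-repeat report.
#'
#' @param report A [control_region_report()] result.
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_control_region_reports <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  motif_tab <- do.call(rbind, lapply(names(report$motifs), function(m) {
    h <- report$motifs[[m]]
    data.frame(motif = m, count = h$count,
               positions = paste(h$positions, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  p1 <- file.path(dir, "cr_motifs.tsv")
  write.table(motif_tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "cr_tandem_repeats.tsv")
  write.table(report$tandem_repeats, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2))
}
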