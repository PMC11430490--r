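#' Base counts of a DNA string
#'
#' Exact counts of `A`, `C`, `G`, `T`; ambiguous bases (`N`) are tallied
#' separately and excluded from every composition denominator downstream.
#'
#' @param seq Uppercase DNA string over `A,C,G,T,N`.
#' @return Named integer vector with elements `A`, `C`, `G`, `T`, `N`.
#' @export
base_counts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("non-DNA character '%s' at position %d", chars[bad], bad))
  }
  setNames(tabulate(idx, nbins = 5L), c("A", "C", "G", "T", "N"))
}

#' Composition and skew profile of a region
#'
#' Computes A+T content and the two strand-asymmetry statistics used
#' throughout mitogenome descriptions:
#' \deqn{AT\mbox{-}skew = (A - T)/(A + T), \quad GC\mbox{-}skew = (G - C)/(G + C)}
#' together with `at_content = (A + T)/(A + C + G + T)`. Values are kept at
#' full precision; rounding happens only in report writers.
#'
#' @param seq Uppercase DNA string with at least one unambiguous base.
#' @param region_name Label for the region.
#' @return One-row `data.frame` of class `CompositionProfile` with columns
#'   `region`, `length`, `A`, `C`, `G`, `T`, `n_ambiguous`, `at_content`,
#'   `at_skew`, `gc_skew`. A skew whose denominator is zero is `NA`.
#' @examples
#' skew_profile("GGGC", "toy")$gc_skew  # 0.5
#' @export
skew_profile <- function(seq, region_name = "region") {
  cnt <- base_counts(seq)
  profile_from_counts(cnt, region_name)
}

profile_from_counts <- function(cnt, region_name) {
  a <- cnt[["A"]]; c_ <- cnt[["C"]]; g <- cnt[["G"]]; t <- cnt[["T"]]
  n_unambig <- a + c_ + g + t
  if (n_unambig == 0L) {
    stop(sprintf("region '%s' has no unambiguous bases", region_name))
  }
  out <- data.frame(
    region = region_name,
    length = n_unambig + cnt[["N"]],
    A = a, C = c_, G = g, T = t, n_ambiguous = cnt[["N"]],
    at_content = (a + t) / n_unambig,
    at_skew = if (a + t > 0L) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0L) (g - c_) / (g + c_) else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("CompositionProfile", "data.frame")
  out
}

#' Composition profiles for a genome and its annotated regions
#'
#' One profile for the whole genome, one for the concatenation of all
#' protein-coding genes (in genome order, each contributing its
#' coding-strand sequence, so L-strand genes such as `nad6` enter as the
#' reverse complement), one per rRNA, one for the control region, and one
#' per individual feature. Overlapping bases count once per region they
#' belong to, so gene-wise totals are preserved. Missing classes are skipped
#' with a warning.
#'
#' @param g A [circular_sequence()].
#' @param ann A [mitogenome_annotation()].
#' @return `data.frame` (stacked [skew_profile()] rows): `whole_genome`,
#'   `PCG_concatenated`, the rRNAs, `control_region`, then every feature by
#'   name.
#' @export
region_profiles <- function(g, ann) {
  stopifnot(inherits(g, "CircularSequence"),
            inherits(ann, "MitogenomeAnnotation"))
  f <- ann$features
  rows <- list(skew_profile(g$residues, "whole_genome"))

  pcg_idx <- which(f$class == "PCG")
  if (length(pcg_idx)) {
    pcg_seq <- paste(vapply(pcg_idx, function(i)
      extract_feature_sequence(g, f[i, ]), character(1)), collapse = "")
    rows[[length(rows) + 1L]] <- skew_profile(pcg_seq, "PCG_concatenated")
  } else {
    warning("no PCG features; PCG aggregate skipped")
  }
  for (cls in c("rRNA", "control_region")) {
    idx <- which(f$class == cls)
    if (!length(idx) && cls == "control_region") {
      warning("no control region feature; its profile skipped")
    }
    for (i in idx) {
      nm <- if (cls == "control_region") "control_region" else f$name[i]
      rows[[length(rows) + 1L]] <-
        skew_profile(extract_feature_sequence(g, f[i, ]), nm)
    }
  }
  for (i in seq_len(nrow(f))) {
    rows[[length(rows) + 1L]] <-
      skew_profile(extract_feature_sequence(g, f[i, ]),
                   paste0("feature:", f$name[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window skew along a circular genome
#'
#' Windows advance by `step` and wrap through the origin, so every position
#' contributes to the same number of windows; the number of rows is
#' `ceiling(L / step)`.
#'
#' @param g A [circular_sequence()].
#' @param window Window width in bp (`<= L`).
#' @param step Step between window starts in bp.
#' @return `data.frame` with columns `center` (1-based genome position of
#'   the window midpoint), `at_skew`, `gc_skew`.
#' @export
sliding_window_skew <- function(g, window, step = window) {
  stopifnot(inherits(g, "CircularSequence"))
  window <- as.integer(window); step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  L <- g$length
  if (window > L) stop("window exceeds genome length")
  ext <- paste0(g$residues, substr(g$residues, 1L, window - 1L))
  starts <- seq.int(1L, L, by = step)
  res <- lapply(starts, function(s) {
    cnt <- base_counts(substr(ext, s, s + window - 1L))
    a <- cnt[["A"]]; t <- cnt[["T"]]; g_ <- cnt[["G"]]; c_ <- cnt[["C"]]
    c(at = if (a + t > 0) (a - t) / (a + t) else NA_real_,
      gc = if (g_ + c_ > 0) (g_ - c_) / (g_ + c_) else NA_real_)
  })
  m <- do.call(rbind, res)
  data.frame(
    center = ((starts + window %/% 2L - 1L) %% L) + 1L,
    at_skew = m[, "at"], gc_skew = m[, "gc"]
  )
}

#' Write composition profiles
#'
#' TSV (percentages and skews rounded to 2 and 5 decimals respectively, the
#' layout of standard mitogenome composition tables) plus a full-precision
#' JSON twin.
#'
#' @param profiles Result of [region_profiles()].
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_composition_reports <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- profiles
  tab$at_percent <- round(100 * tab$at_content, 2L)
  tab$at_content <- NULL
  tab$at_skew <- round(tab$at_skew, 5L)
  tab$gc_skew <- round(tab$gc_skew, 5L)
  p1 <- file.path(dir, "composition.tsv")
  write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "composition.json")
  jsonlite::write_json(profiles, p2, digits = NA, pretty = TRUE)
  invisible(c(p1, p2))
}
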