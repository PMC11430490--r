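#' Call variants from a global alignment
#'
#' Scans alignment columns and emits one record per difference:
#' substitutions column by column, and runs of adjacent gap columns merged
#' into single insertion/deletion records. Indels are left-aligned (shifted
#' to the lowest equivalent reference position, as in VCF normalization) so
#' that calls are comparable across callers and with implanted-mutation
#' truth sets. Each record is assigned to the annotated feature covering its
#' position, or `"intergenic"`.
#'
#' Record conventions (mirroring the dot notation of mutation tables):
#' a substitution has equal-length `ref_allele`/`alt_allele`; a deletion has
#' `alt_allele = "."` and `ref_position` pointing at its first deleted base;
#' an insertion has `ref_allele = "."` and `ref_position` pointing at the
#' reference base immediately *before* the inserted bases (0 when the
#' insertion precedes the first base).
#'
#' @param aln An [global_align()] result whose `ref` is the annotated
#'   genome.
#' @param ann A [mitogenome_annotation()] for the reference, or `NULL` to
#'   skip feature assignment.
#' @return `data.frame` with columns `ref_position`, `type`
#'   (`substitution`/`insertion`/`deletion`), `ref_allele`, `alt_allele`,
#'   `feature_name`.
#' @export
call_variants <- function(aln, ann = NULL) {
  stopifnot(inherits(aln, "AlignmentResult"))
  ra <- strsplit(aln$ref, "", fixed = TRUE)[[1L]]
  qa <- strsplit(aln$query, "", fixed = TRUE)[[1L]]
  stopifnot(length(ra) == length(qa))
  refseq <- paste(ra[ra != "-"], collapse = "")
  rpos <- cumsum(ra != "-")  # reference coordinate of each column

  recs <- list()
  add <- function(pos, type, ref_allele, alt_allele) {
    recs[[length(recs) + 1L]] <<- data.frame(
      ref_position = pos, type = type, ref_allele = ref_allele,
      alt_allele = alt_allele, stringsAsFactors = FALSE)
  }

  sub_cols <- which(ra != "-" & qa != "-" & ra != qa)
  for (i in sub_cols) add(rpos[i], "substitution", ra[i], qa[i])

  gap_kind <- ifelse(ra == "-", "ins", ifelse(qa == "-", "del", "none"))
  r <- rle(gap_kind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    kind <- r$values[k]
    if (kind == "none") next
    cols <- starts[k]:ends[k]
    if (kind == "del") {
      seg <- paste(ra[cols], collapse = "")
      la <- left_align_indel(refseq, rpos[cols[1L]], seg, "deletion")
      add(la$pos, "deletion", la$seg, ".")
    } else {
      seg <- paste(qa[cols], collapse = "")
      anchor <- rpos[cols[1L]]  # last ref base consumed before the run
      la <- left_align_indel(refseq, anchor, seg, "insertion")
      add(la$pos, "insertion", ".", la$seg)
    }
  }
  if (!length(recs)) {
    out <- data.frame(ref_position = integer(0), type = character(0),
                      ref_allele = character(0), alt_allele = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, recs)
    out <- out[order(out$ref_position, out$type), , drop = FALSE]
    rownames(out) <- NULL
  }
  out$feature_name <- if (is.null(ann)) {
    rep(NA_character_, nrow(out))
  } else {
    vapply(seq_len(nrow(out)), function(i) {
      pos <- variant_anchor_position(out[i, ])
      hits <- covering_features(ann, pos)
      if (length(hits)) hits[1L] else "intergenic"
    }, character(1))
  }
  out
}

## For feature lookup: substitutions/deletions use their first reference
## base; insertions use the base after the insertion point.
variant_anchor_position <- function(v) {
  if (v$type == "insertion") v$ref_position + 1L else v$ref_position
}

## Shift an indel to its lowest equivalent reference position.
## Deletion of refseq[pos .. pos+k-1]: shifting left by one is equivalent
## iff refseq[pos-1] == refseq[pos+k-1]. Insertion of `seg` after `pos`:
## equivalent iff refseq[pos] equals the last char of `seg`, which then
## rotates to the front.
left_align_indel <- function(refseq, pos, seg, type) {
  k <- nchar(seg)
  if (type == "deletion") {
    while (pos > 1L &&
           substr(refseq, pos - 1L, pos - 1L) ==
           substr(refseq, pos + k - 1L, pos + k - 1L)) {
      pos <- pos - 1L
      seg <- substr(refseq, pos, pos + k - 1L)
    }
  } else {
    while (pos >= 1L &&
           substr(refseq, pos, pos) == substr(seg, k, k)) {
      seg <- paste0(substr(seg, k, k), substr(seg, 1L, k - 1L))
      pos <- pos - 1L
    }
  }
  list(pos = as.integer(pos), seg = seg)
}

#' Apply variant records to a reference sequence
#'
#' Reconstructs the query implied by a set of non-overlapping variant
#' records (the round-trip inverse of [call_variants()]).
#'
#' @param refseq Reference DNA string.
#' @param variants `data.frame` as returned by [call_variants()].
#' @return The edited DNA string.
#' @export
apply_variants <- function(refseq, variants) {
  if (!nrow(variants)) return(refseq)
  chars <- strsplit(refseq, "", fixed = TRUE)[[1L]]
  keep <- rep(TRUE, length(chars))
  ins_after <- rep("", length(chars) + 1L)  # ins_after[p+1] goes after base p
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$type == "substitution") {
      k <- nchar(v$alt_allele)
      idx <- v$ref_position:(v$ref_position + k - 1L)
      chars[idx] <- strsplit(v$alt_allele, "", fixed = TRUE)[[1L]]
    } else if (v$type == "deletion") {
      k <- nchar(v$ref_allele)
      keep[v$ref_position:(v$ref_position + k - 1L)] <- FALSE
    } else {
      ins_after[v$ref_position + 1L] <- paste0(ins_after[v$ref_position + 1L],
                                               v$alt_allele)
    }
  }
  pieces <- character(2L * length(chars) + 1L)
  pieces[1L] <- ins_after[1L]
  pieces[2L * seq_along(chars)] <- ifelse(keep, chars, "")
  pieces[2L * seq_along(chars) + 1L] <- ins_after[seq_along(chars) + 1L]
  paste(pieces, collapse = "")
}

#' Annotate codon-level consequences of variants
#'
#' Maps each variant onto every feature covering it (a variant inside the
#' `atp8`/`atp6` overlap yields one record per gene) and derives its effect.
#' Substitutions in protein-coding genes have their codon recomputed on the
#' coding strand and are classified `synonymous` or `missense` by
#' translation; indels whose length is not a multiple of 3 are
#' `frameshift`, in-frame indels are `inframe`; variants in tRNA/rRNA genes
#' are `rna`; control-region and intergenic variants are `noncoding`.
#' `codon_index` is the 1-based codon number within the gene.
#'
#' @param variants `data.frame` from [call_variants()].
#' @param ann A [mitogenome_annotation()].
#' @param g The reference [circular_sequence()].
#' @param code A [mito_genetic_code()].
#' @return `data.frame` with columns `ref_position`, `type`, `gene`,
#'   `codon_index`, `ref_aa`, `alt_aa`, `effect`.
#' @export
annotate_consequences <- function(variants, ann, g,
                                  code = mito_genetic_code()) {
  stopifnot(inherits(ann, "MitogenomeAnnotation"),
            inherits(g, "CircularSequence"))
  L <- g$length
  f <- ann$features
  rows <- list()
  emit <- function(v, gene, codon_index, ref_aa, alt_aa, effect) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ref_position = v$ref_position, type = v$type, gene = gene,
      codon_index = codon_index, ref_aa = ref_aa, alt_aa = alt_aa,
      effect = effect, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$ref_position < 0L || v$ref_position > L) {
      stop(sprintf("variant position %d outside [1, %d]", v$ref_position, L))
    }
    pos <- variant_anchor_position(v)
    hit_names <- covering_features(ann, pos)
    if (!length(hit_names)) {
      emit(v, "intergenic", NA_integer_, ".", ".", "noncoding")
      next
    }
    for (nm in hit_names) {
      feat <- f[f$name == nm, ]
      if (feat$class %in% c("tRNA", "rRNA")) {
        emit(v, nm, NA_integer_, ".", ".", "rna")
      } else if (feat$class == "control_region") {
        emit(v, nm, NA_integer_, ".", ".", "noncoding")
      } else {
        cons <- pcg_consequence(v, feat, g, code)
        emit(v, nm, cons$codon_index, cons$ref_aa, cons$alt_aa, cons$effect)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(ref_position = integer(0), type = character(0),
                      gene = character(0), codon_index = integer(0),
                      ref_aa = character(0), alt_aa = character(0),
                      effect = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pcg_consequence <- function(v, feat, g, code) {
  L <- g$length
  positions <- feature_positions(feat, L)  # genome coords, H-strand order
  cds <- extract_feature_sequence(g, feat)
  len <- nchar(cds)
  pos <- variant_anchor_position(v)
  h_off <- match(pos, positions)
  offset <- if (feat$strand == "+") h_off else len - h_off + 1L
  codon_index <- (offset - 1L) %/% 3L + 1L
  if (v$type != "substitution") {
    k <- nchar(if (v$type == "deletion") v$ref_allele else v$alt_allele)
    effect <- if (k %% 3L == 0L) "inframe" else "frameshift"
    return(list(codon_index = codon_index, ref_aa = ".", alt_aa = ".",
                effect = effect))
  }
  cstart <- 3L * (codon_index - 1L) + 1L
  if (cstart + 2L > len) {  # incomplete terminal codon
    return(list(codon_index = codon_index, ref_aa = ".", alt_aa = ".",
                effect = "synonymous"))
  }
  ref_codon <- substr(cds, cstart, cstart + 2L)
  alt_base <- if (feat$strand == "+") v$alt_allele else
    chartr("ACGTN", "TGCAN", v$alt_allele)
  within <- offset - cstart + 1L
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  ref_aa <- unname(code$codon_to_aa[ref_codon])
  alt_aa <- unname(code$codon_to_aa[alt_codon])
  if (is.na(ref_aa)) ref_aa <- "X"
  if (is.na(alt_aa)) alt_aa <- "X"
  list(codon_index = codon_index, ref_aa = ref_aa, alt_aa = alt_aa,
       effect = if (identical(ref_aa, alt_aa)) "synonymous" else "missense")
}

#' Summarize a pairwise comparison
#'
#' @param variants `data.frame` from [call_variants()].
#' @param consequences `data.frame` from [annotate_consequences()].
#' @param ann Optional annotation, used to count variants by feature class.
#' @return List of class `DiffSummary`: `n_variants`, `n_substitutions`,
#'   `n_insertions`, `n_deletions`, `by_feature_class` (named counts),
#'   `n_aa_changing` (variant positions whose effect is missense,
#'   frameshift or inframe in at least one gene).
#' @export
diff_summary <- function(variants, consequences, ann = NULL) {
  type_n <- function(t) sum(variants$type == t)
  by_class <- NULL
  if (!is.null(ann) && nrow(variants)) {
    cls_of <- setNames(ann$features$class, ann$features$name)
    cls <- ifelse(variants$feature_name %in% names(cls_of),
                  cls_of[variants$feature_name], "intergenic")
    by_class <- table(cls)
  } else if (nrow(variants) == 0L) {
    by_class <- table(character(0))
  }
  changing <- unique(consequences$ref_position[
    consequences$effect %in% c("missense", "frameshift", "inframe")])
  structure(list(
    n_variants = nrow(variants),
    n_substitutions = type_n("substitution"),
    n_insertions = type_n("insertion"),
    n_deletions = type_n("deletion"),
    by_feature_class = by_class,
    n_aa_changing = length(changing)
  ), class = "DiffSummary")
}

#' @export
print.DiffSummary <- function(x, ...) {
  cat(sprintf(
    "DiffSummary: %d variants (%d substitutions, %d insertions, %d deletions); %d amino-acid-changing position(s)\n",
    x$n_variants, x$n_substitutions, x$n_insertions, x$n_deletions,
    x$n_aa_changing))
  invisible(x)
}

#' Compare two mitogenomes end to end
#'
#' Optionally rotates both genomes to a shared anchor (required when the
#' two sequences were linearized at different origins), globally aligns
#' them, calls variants on the reference coordinate system, annotates
#' consequences and summarizes.
#'
#' @param ref A [circular_sequence()] (the annotated reference).
#' @param ann The reference [mitogenome_annotation()].
#' @param query A [circular_sequence()].
#' @param anchor Optional anchor sequence passed to [rotate_to_anchor()]
#'   for both genomes.
#' @param code A [mito_genetic_code()].
#' @param band,match,mismatch,gap_open,gap_extend Passed to
#'   [global_align()]. The default band (200 bp) is far wider than the
#'   cumulative indel offset between conspecific mitogenomes.
#' @return List of class `MitoComparison`: `alignment`, `variants`,
#'   `consequences`, `summary`.
#' @export
compare_genomes <- function(ref, ann, query, anchor = NULL,
                            code = mito_genetic_code(), band = 200L,
                            match = 1, mismatch = -1, gap_open = -4,
                            gap_extend = -1) {
  stopifnot(inherits(ref, "CircularSequence"),
            inherits(query, "CircularSequence"))
  if (!is.null(anchor)) {
    rot <- rotate_to_anchor(ref, anchor, ann)
    ref <- rot$genome; ann <- rot$annotation
    query <- rotate_to_anchor(query, anchor)
  }
  aln <- global_align(ref$residues, query$residues, match = match,
                      mismatch = mismatch, gap_open = gap_open,
                      gap_extend = gap_extend, band = band)
  variants <- call_variants(aln, ann)
  consequences <- annotate_consequences(variants, ann, ref, code)
  structure(list(
    alignment = aln, variants = variants, consequences = consequences,
    summary = diff_summary(variants, consequences, ann)
  ), class = "MitoComparison")
}

#' @export
print.MitoComparison <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Write variant and consequence reports
#'
#' TSV tables plus a minimal VCF (CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO
#' with `FEATURE` and `TYPE` tags). In the VCF, indels are emitted in the
#' usual anchored-base representation.
#'
#' @param cmp A [compare_genomes()] result.
#' @param ref The reference [circular_sequence()] (for VCF anchor bases).
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_variant_reports <- function(cmp, ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "variants.tsv")
  write.table(cmp$variants, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "consequences.tsv")
  write.table(cmp$consequences, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p3 <- file.path(dir, "variants.vcf")
  writeLines(format_vcf(cmp$variants, ref), p3)
  invisible(c(p1, p2, p3))
}

format_vcf <- function(variants, ref) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$id, ref$length),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=FEATURE,Number=1,Type=String,Description=\"Covering feature\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (!nrow(variants)) return(hdr)
  base_at <- function(p) substr(ref$residues, p, p)
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$type == "substitution") {
      pos <- v$ref_position; refa <- v$ref_allele; alta <- v$alt_allele
    } else if (v$type == "deletion") {
      pos <- max(v$ref_position - 1L, 1L)
      refa <- paste0(base_at(pos), v$ref_allele)
      alta <- base_at(pos)
    } else {
      pos <- max(v$ref_position, 1L)
      refa <- base_at(pos)
      alta <- paste0(base_at(pos), v$alt_allele)
    }
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s;FEATURE=%s",
            ref$id, pos, refa, alta, v$type, v$feature_name)
  }, character(1))
  c(hdr, rows)
}
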