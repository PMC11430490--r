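#' Layout specification for a synthetic circular mitogenome
#'
#' A layout is an ordered table of features around the circle: for each
#' feature its name, class, length, strand, and the signed gap to the next
#' feature (negative = overlap). The genome length is implied:
#' `sum(length) + sum(gap_to_next)`, counting the gap of the last feature
#' back to the first.
#'
#' @param features `data.frame` with columns `name`, `class`, `length`,
#'   `strand`, `gap_to_next`.
#' @return Object of class `LayoutSpec` (the validated `data.frame` with a
#'   `genome_length` attribute).
#' @export
layout_spec <- function(features) {
  need <- c("name", "class", "length", "strand", "gap_to_next")
  stopifnot(is.data.frame(features), all(need %in% names(features)))
  features <- features[, need]
  features$length <- as.integer(features$length)
  features$gap_to_next <- as.integer(features$gap_to_next)
  if (any(features$length < 1L)) stop("feature lengths must be positive")
  if (anyDuplicated(features$name)) stop("duplicate feature names in layout")
  n <- nrow(features)
  nxt <- c(seq_len(n)[-1L], 1L)
  too_deep <- -features$gap_to_next >=
    pmin(features$length, features$length[nxt])
  if (any(features$gap_to_next < 0L & too_deep)) {
    stop("overlap longer than one of the overlapping features: ",
         paste(features$name[features$gap_to_next < 0L & too_deep],
               collapse = ", "))
  }
  L <- sum(features$length) + sum(features$gap_to_next)
  if (L < n) stop("layout implies an impossibly short genome")
  structure(features, class = c("LayoutSpec", "data.frame"),
            genome_length = L)
}

#' Default layout: the 37-gene douc langur mitogenome arrangement
#'
#' The canonical vertebrate mitochondrial gene order as annotated in the
#' grey-shanked douc langur (*Pygathrix cinerea*) reference mitogenome:
#' 13 protein-coding genes, 22 tRNAs and 2 rRNAs plus a 1094 bp
#' origin-spanning control region, with the published inter-feature gaps
#' and overlaps (including the characteristic 22 bp `atp8`/`atp6` overlap),
#' for a total circular length of 16,541 bp. `nad6` and eight tRNAs lie on
#' the L strand.
#'
#' @return A [layout_spec()] with 38 rows (37 genes + control region).
#' @examples
#' attr(default_layout(), "genome_length")  # 16541
#' @export
default_layout <- function() {
  f <- data.frame(
    name = c("trnF", "rrnS", "trnV", "rrnL", "trnL2", "nad1", "trnI",
             "trnQ", "trnM", "nad2", "trnW", "trnA", "trnN", "trnC",
             "trnY", "cox1", "trnS2", "trnD", "cox2", "trnK", "atp8",
             "atp6", "cox3", "trnG", "nad3", "trnR", "nad4l", "nad4",
             "trnH", "trnS1", "trnL1", "nad5", "nad6", "trnE", "cob",
             "trnT", "trnP", "control_region"),
    class = c("tRNA", "rRNA", "tRNA", "rRNA", "tRNA", "PCG", "tRNA",
              "tRNA", "tRNA", "PCG", "tRNA", "tRNA", "tRNA", "tRNA",
              "tRNA", "PCG", "tRNA", "tRNA", "PCG", "tRNA", "PCG",
              "PCG", "PCG", "tRNA", "PCG", "tRNA", "PCG", "PCG",
              "tRNA", "tRNA", "tRNA", "PCG", "PCG", "tRNA", "PCG",
              "tRNA", "tRNA", "control_region"),
    length = c(71L, 949L, 66L, 1565L, 75L, 951L, 70L, 72L, 68L, 1038L,
               67L, 69L, 73L, 66L, 65L, 1542L, 69L, 69L, 660L, 68L,
               183L, 675L, 783L, 67L, 345L, 65L, 294L, 1368L, 69L, 59L,
               71L, 1800L, 519L, 69L, 1134L, 65L, 67L, 1094L),
    strand = c("+", "+", "+", "+", "+", "+", "+", "-", "+", "+", "+",
               "-", "-", "-", "-", "+", "-", "+", "+", "+", "+", "+",
               "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "-",
               "-", "+", "+", "-", "+"),
    gap_to_next = c(0L, 0L, -2L, 0L, 2L, 4L, -3L, 0L, 0L, 4L, 7L, 1L,
                    32L, 0L, 1L, 0L, 3L, 1L, 68L, 1L, -22L, 5L, 1L, 0L,
                    1L, 0L, -4L, 10L, 0L, 0L, 3L, 15L, 0L, 4L, 7L, 2L,
                    0L, 0L),
    stringsAsFactors = FALSE
  )
  layout_spec(f)
}

## Coordinates realized by a layout on the circle, with the first feature
## starting at `first_start` (1-based, taken modulo L).
layout_coordinates <- function(layout, first_start = 137L) {
  L <- attr(layout, "genome_length")
  n <- nrow(layout)
  wrap1 <- function(p) ((p - 1L) %% L) + 1L
  start <- integer(n); stop_ <- integer(n)
  s <- wrap1(first_start)
  for (i in seq_len(n)) {
    start[i] <- s
    stop_[i] <- wrap1(s + layout$length[i] - 1L)
    s <- wrap1(stop_[i] + layout$gap_to_next[i] + 1L)
  }
  if (s != start[1L]) {
    stop("layout does not close the circle (internal error)")
  }
  mitogenome_annotation(
    data.frame(name = layout$name, class = layout$class, start = start,
               stop = stop_, strand = layout$strand,
               stringsAsFactors = FALSE),
    L
  )
}

base_probs <- function(at, a_balance = 0.5, g_balance = 0.5) {
  c(A = at * a_balance, C = (1 - at) * (1 - g_balance),
    G = (1 - at) * g_balance, T = at * (1 - a_balance))
}

sample_bases <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

## Exact-count background: a shuffled multiset realizing the target
## composition as closely as rounding allows, so realized genome-wide A+T
## content is tight around the target.
sample_bases_exact <- function(n, at, a_balance = 0.5, g_balance = 0.5) {
  n_at <- round(at * n)
  n_a <- round(a_balance * n_at)
  n_gc <- n - n_at
  n_g <- round(g_balance * n_gc)
  pool <- c(rep("A", n_a), rep("T", n_at - n_a),
            rep("G", n_g), rep("C", n_gc - n_g))
  sample(pool, n)
}

## One random sense (non-stop) codon as 3 bases.
sample_sense_codons <- function(n, probs, stop_codons) {
  out <- character(0)
  while (length(out) < n) {
    draw <- matrix(sample_bases(3L * (n - length(out) + 8L), probs),
                   ncol = 3L, byrow = TRUE)
    cods <- paste0(draw[, 1L], draw[, 2L], draw[, 3L])
    out <- c(out, cods[!cods %in% stop_codons])
  }
  out[seq_len(n)]
}

## Random coding sequence: ATG start, sense interior, TAA stop (or an
## incomplete T/TA stop when the length is not a multiple of 3).
random_cds <- function(len, probs, stop_codons) {
  rem <- len %% 3L
  n_codons <- len %/% 3L
  if (n_codons < 2L) stop("PCG length must allow a start and a stop codon")
  tail_ <- if (rem == 0L) "TAA" else substr("TA", 1L, rem)
  n_interior <- n_codons - 1L - (if (rem == 0L) 1L else 0L)
  paste0("ATG",
         paste(sample_sense_codons(n_interior, probs, stop_codons),
               collapse = ""),
         tail_)
}

write_coding <- function(chars, feat, L, cds) {
  positions <- feature_positions(feat, L)
  bases <- strsplit(cds, "", fixed = TRUE)[[1L]]
  if (feat$strand == "-") {
    bases <- rev(chartr("ACGTN", "TGCAN", bases))
  }
  chars[positions] <- bases
  chars
}

read_coding <- function(chars, feat, L) {
  positions <- feature_positions(feat, L)
  s <- paste(chars[positions], collapse = "")
  if (feat$strand == "-") revcomp(s) else s
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds a random circular genome realizing a [layout_spec()] exactly:
#' every protein-coding gene starts with `ATG`, ends with `TAA` (or an
#' incomplete `T`/`TA` stop for lengths not divisible by 3) and has no
#' internal stop under the vertebrate mitochondrial code; tRNA, rRNA,
#' control-region and spacer positions are plain background sequence (no
#' secondary-structure realism). Where genes overlap, both genes'
#' constraints are satisfied when jointly possible; otherwise later genes
#' win and a warning names the loser (with the published layout, `nad4`'s
#' start codon makes a complete `nad4l` stop codon impossible, matching
#' real annotations). Background composition is balanced after the coding
#' regions are drawn so that realized genome-wide A+T content lands within
#' rounding of `at_target`.
#'
#' @param layout A [layout_spec()]; defaults to [default_layout()].
#' @param at_target Target genome-wide A+T fraction (0-1, exclusive).
#' @param seed Integer seed; generation is deterministic given
#'   `layout + at_target + seed`.
#' @param a_balance,g_balance Fraction of A among A+T and of G among G+C in
#'   the background (0.5 = no skew).
#' @param first_start Genome position of the first layout feature; the
#'   default places the published douc layout at its published
#'   coordinates, with the control region spanning the origin.
#' @param id Identifier for the generated genome.
#' @return List with `genome` ([circular_sequence()]) and `annotation`
#'   ([mitogenome_annotation()]).
#' @export
generate_genome <- function(layout = default_layout(), at_target = 0.614,
                            seed = 1L, a_balance = 0.5, g_balance = 0.5,
                            first_start = 137L, id = "synthetic_mitogenome") {
  stopifnot(inherits(layout, "LayoutSpec"))
  if (!(at_target > 0 && at_target < 1)) stop("at_target must be in (0, 1)")
  ann <- layout_coordinates(layout, first_start)
  L <- ann$genome_length
  code <- mito_genetic_code()
  withr::with_seed(as.integer(seed), {
    probs <- base_probs(at_target, a_balance, g_balance)
    chars <- character(L)
    f <- ann$features
    ## order features as in the layout (genome order around the circle)
    ord <- match(layout$name, f$name)
    pcg_rows <- ord[layout$class == "PCG"]
    for (i in pcg_rows) {
      cds <- random_cds(feature_length(f[i, ], L), probs, code$stop_codons)
      chars <- write_coding(chars, f[i, ], L, cds)
    }
    chars <- repair_pcg_constraints(chars, f, pcg_rows, L, probs, code)
    pcg_positions <- sort(unique(unlist(
      lapply(pcg_rows, function(i) feature_positions(f[i, ], L)))))
    noncoding <- setdiff(seq_len(L), pcg_positions)
    if (length(noncoding)) {
      at_pcg <- sum(chars[pcg_positions] %in% c("A", "T"))
      need <- round(at_target * L) - at_pcg
      frac <- min(max(need / length(noncoding), 0.02), 0.98)
      chars[noncoding] <- sample_bases_exact(length(noncoding), frac,
                                             a_balance, g_balance)
    }
    genome <- circular_sequence(paste(chars, collapse = ""), id = id)
    list(genome = genome, annotation = ann)
  })
}

## Enforce start/stop/no-internal-stop on PCGs after overlaps have been
## written. Start codons are immutable anchors; stops and internal stops
## are fixed by direct assignment or resampling of positions not locked by
## another gene's start codon, rechecking all genes each round.
repair_pcg_constraints <- function(chars, f, pcg_rows, L, probs, code) {
  ## start codons are immutable anchors: no gene may rewrite another
  ## gene's start codon positions
  start_owner <- integer(L)
  for (i in pcg_rows) {
    pos <- feature_positions(f[i, ], L)
    cod <- if (f$strand[i] == "-") rev(pos)[1:3] else pos[1:3]
    start_owner[cod] <- i
  }
  free_for <- function(gpos, row) {
    start_owner[gpos] == 0L | start_owner[gpos] == row
  }
  codon_positions <- function(feat, codon_index) {
    pos <- feature_positions(feat, L)
    if (feat$strand == "-") pos <- rev(pos)
    pos[(3L * (codon_index - 1L) + 1L):(3L * codon_index)]
  }
  set_codon <- function(chars, feat, row, codon_index, codon) {
    gpos <- codon_positions(feat, codon_index)
    bases <- strsplit(codon, "", fixed = TRUE)[[1L]]
    if (feat$strand == "-") bases <- chartr("ACGTN", "TGCAN", bases)
    free <- free_for(gpos, row)
    chars[gpos[free]] <- bases[free]
    chars
  }
  violations <- function(chars) {
    out <- list()
    for (i in pcg_rows) {
      s <- read_coding(chars, f[i, ], L)
      n_codons <- nchar(s) %/% 3L
      rem <- nchar(s) %% 3L
      if (substr(s, 1L, 3L) != "ATG") {
        out[[length(out) + 1L]] <- list(row = i, kind = "start", codon = 1L)
      }
      cods <- split_codons(s)$codons
      last_full <- n_codons
      for (ci in seq_len(n_codons)) {
        is_stop <- cods[ci] %in% code$stop_codons
        if (ci < last_full || rem > 0L) {
          if (is_stop) {
            out[[length(out) + 1L]] <- list(row = i, kind = "internal_stop",
                                            codon = ci)
          }
        } else if (cods[ci] != "TAA") {
          out[[length(out) + 1L]] <- list(row = i, kind = "stop", codon = ci)
        }
      }
      if (rem > 0L) {
        tail_ <- substr(s, 3L * n_codons + 1L, nchar(s))
        if (tail_ != substr("TA", 1L, rem)) {
          out[[length(out) + 1L]] <- list(row = i, kind = "tail",
                                          codon = n_codons + 1L)
        }
      }
    }
    out
  }
  seen <- character(0)
  for (iter in 1:300) {
    v <- violations(chars)
    v <- Filter(function(x) {
      !paste(x$row, x$kind, x$codon) %in% seen
    }, v)
    if (!length(v)) break
    x <- v[[1L]]
    key <- paste(x$row, x$kind, x$codon)
    feat <- f[x$row, ]
    if (x$kind %in% c("start", "stop")) {
      target <- if (x$kind == "start") "ATG" else "TAA"
      chars <- set_codon(chars, feat, x$row, x$codon, target)
      if (!identical(check_codon(chars, feat, L, x$codon), target)) {
        seen <- c(seen, key)
        warning(sprintf(
          "PCG '%s': cannot realize %s codon (locked by an overlapping gene's start)",
          feat$name, x$kind))
      }
    } else if (x$kind == "tail") {
      gpos_all <- feature_positions(feat, L)
      if (feat$strand == "-") gpos_all <- rev(gpos_all)
      n <- length(gpos_all)
      rem <- n %% 3L
      gpos <- gpos_all[(n - rem + 1L):n]
      bases <- strsplit(substr("TA", 1L, rem), "", fixed = TRUE)[[1L]]
      if (feat$strand == "-") bases <- chartr("ACGTN", "TGCAN", bases)
      free <- free_for(gpos, x$row)
      chars[gpos[free]] <- bases[free]
      if (!all(free)) {
        seen <- c(seen, key)
        warning(sprintf("PCG '%s': cannot realize incomplete stop", feat$name))
      }
    } else {  # internal stop: resample free positions until not a stop
      gpos <- codon_positions(feat, x$codon)
      free <- free_for(gpos, x$row)
      if (!any(free)) {
        seen <- c(seen, key)
        warning(sprintf("PCG '%s': internal stop at codon %d is locked",
                        feat$name, x$codon))
      } else {
        fixed_ok <- FALSE
        for (try in 1:50) {
          chars[gpos[free]] <- sample_bases(sum(free), probs)
          if (!check_codon(chars, feat, L, x$codon) %in% code$stop_codons) {
            fixed_ok <- TRUE
            break
          }
        }
        if (!fixed_ok) seen <- c(seen, key)
      }
    }
  }
  chars
}

check_codon <- function(chars, feat, L, codon_index) {
  s <- read_coding(chars, feat, L)
  substr(s, 3L * (codon_index - 1L) + 1L, 3L * codon_index)
}

#' Mutation plan for a synthetic genome pair
#'
#' @param n_substitutions,n_insertions,n_deletions Event counts. The
#'   defaults (30/4/9) mirror the scale of differences reported between
#'   conspecific douc langur mitogenomes (43 variant positions).
#' @param max_indel Maximum indel length in bp.
#' @param min_spacing Minimum spacing between event positions in bp; also
#'   keeps events away from the linearization origin so a linear global
#'   alignment sees every event in context.
#' @param seed Integer seed.
#' @return List of class `MutationPlan`.
#' @export
mutation_plan <- function(n_substitutions = 30L, n_insertions = 4L,
                          n_deletions = 9L, max_indel = 3L,
                          min_spacing = 50L, seed = 7L) {
  stopifnot(n_substitutions >= 0L, n_insertions >= 0L, n_deletions >= 0L,
            max_indel >= 1L, min_spacing >= 1L)
  structure(list(
    n_substitutions = as.integer(n_substitutions),
    n_insertions = as.integer(n_insertions),
    n_deletions = as.integer(n_deletions),
    max_indel = as.integer(max_indel),
    min_spacing = as.integer(min_spacing),
    seed = as.integer(seed)
  ), class = "MutationPlan")
}

#' Implant mutations into a genome with an exact truth set
#'
#' Draws event positions uniformly with at least `min_spacing` bp between
#' them (and a buffer from the linearization origin), applies them, and
#' returns the mutated genome together with truth variant records in the
#' same normalized representation that [call_variants()] emits, so recovery
#' can be scored exactly.
#'
#' @param g A [circular_sequence()] (the reference).
#' @param ann Its [mitogenome_annotation()] (used to tag truth records with
#'   covering features); may be `NULL`.
#' @param plan A [mutation_plan()].
#' @return List with `genome` (mutated [circular_sequence()]) and `truth`
#'   (`data.frame` with the [call_variants()] columns).
#' @export
mutate_genome <- function(g, ann, plan = mutation_plan()) {
  stopifnot(inherits(g, "CircularSequence"), inherits(plan, "MutationPlan"))
  L <- g$length
  n_events <- plan$n_substitutions + plan$n_insertions + plan$n_deletions
  buffer <- max(plan$min_spacing, plan$max_indel + 2L)
  lo <- buffer + 1L
  hi <- L - buffer
  span_needed <- (n_events - 1L) * plan$min_spacing
  if (n_events > 0L && (hi <= lo || hi - lo < span_needed)) {
    stop("mutation plan infeasible for this genome length")
  }
  refseq <- g$residues
  if (n_events == 0L) {
    return(list(genome = circular_sequence(refseq, id = paste0(g$id, "_mut")),
                truth = empty_variants(ann)))
  }
  withr::with_seed(plan$seed, {
    ## n points with pairwise spacing >= s: sample from a shrunken range,
    ## then fan back out
    raw <- sort(sample.int(hi - lo + 1L - span_needed, n_events))
    pos <- lo + raw - 1L + (seq_len(n_events) - 1L) * plan$min_spacing
    types <- sample(c(rep("substitution", plan$n_substitutions),
                      rep("insertion", plan$n_insertions),
                      rep("deletion", plan$n_deletions)))
    recs <- vector("list", n_events)
    mutseq <- refseq
    for (i in rev(seq_len(n_events))) {  # high to low keeps coords stable
      p <- pos[i]
      if (types[i] == "substitution") {
        ref_b <- substr(refseq, p, p)
        alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
        substr(mutseq, p, p) <- alt_b
        recs[[i]] <- data.frame(ref_position = p, type = "substitution",
                                ref_allele = ref_b, alt_allele = alt_b,
                                stringsAsFactors = FALSE)
      } else if (types[i] == "deletion") {
        k <- sample.int(plan$max_indel, 1L)
        seg <- substr(refseq, p, p + k - 1L)
        mutseq <- paste0(substr(mutseq, 1L, p - 1L),
                         substr(mutseq, p + k, nchar(mutseq)))
        la <- left_align_indel(refseq, p, seg, "deletion")
        recs[[i]] <- data.frame(ref_position = la$pos, type = "deletion",
                                ref_allele = la$seg, alt_allele = ".",
                                stringsAsFactors = FALSE)
      } else {
        k <- sample.int(plan$max_indel, 1L)
        seg <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = "")
        mutseq <- paste0(substr(mutseq, 1L, p), seg,
                         substr(mutseq, p + 1L, nchar(mutseq)))
        la <- left_align_indel(refseq, p, seg, "insertion")
        recs[[i]] <- data.frame(ref_position = la$pos, type = "insertion",
                                ref_allele = ".", alt_allele = la$seg,
                                stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, recs)
    truth <- truth[order(truth$ref_position, truth$type), , drop = FALSE]
    rownames(truth) <- NULL
    truth$feature_name <- if (is.null(ann)) {
      rep(NA_character_, nrow(truth))
    } else {
      vapply(seq_len(nrow(truth)), function(i) {
        hits <- covering_features(ann, variant_anchor_position(truth[i, ]))
        if (length(hits)) hits[1L] else "intergenic"
      }, character(1))
    }
    list(genome = circular_sequence(mutseq, id = paste0(g$id, "_mut")),
         truth = truth)
  })
}

empty_variants <- function(ann = NULL) {
  data.frame(ref_position = integer(0), type = character(0),
             ref_allele = character(0), alt_allele = character(0),
             feature_name = character(0), stringsAsFactors = FALSE)
}

#' Score variant recovery against a truth set
#'
#' Exact-match comparison: a called record counts as a true positive only
#' if its position, type and alleles all equal a truth record (both sides
#' use the same left-aligned normalization).
#'
#' @param called,truth `data.frame`s with the [call_variants()] columns.
#' @return List with `precision`, `recall`, `n_called`, `n_truth`,
#'   `n_matched`.
#' @export
score_recovery <- function(called, truth) {
  key <- function(d) paste(d$ref_position, d$type, d$ref_allele,
                           d$alt_allele)
  matched <- sum(key(called) %in% key(truth))
  list(
    precision = if (nrow(called)) matched / nrow(called) else NA_real_,
    recall = if (nrow(truth)) matched / nrow(truth) else NA_real_,
    n_called = nrow(called), n_truth = nrow(truth), n_matched = matched
  )
}

#' Write a synthetic genome bundle
#'
#' FASTA + feature-table TSV (+ truth-variant TSV when present).
#'
#' @param sim Result of [generate_genome()].
#' @param dir Output directory.
#' @param truth Optional truth `data.frame` from [mutate_genome()].
#' @return Written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "genome.fasta")
  write_fasta(sim$genome, p1)
  p2 <- file.path(dir, "features.tsv")
  write_feature_table(sim$annotation, p2)
  paths <- c(p1, p2)
  if (!is.null(truth)) {
    p3 <- file.path(dir, "truth_variants.tsv")
    write.table(truth, p3, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
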