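#' Annotated feature on a circular genome
#'
#' Coordinates are 1-based and fully inclusive on the heavy (H) strand, the
#' convention used by standard mitogenome annotation tables. A feature with
#' `stop < start` wraps through the sequence origin (a single record, not two
#' segments); in vertebrate mitogenomes this is typically the control region.
#'
#' @param name Feature name, unique within an annotation (e.g. `"nad5"`,
#'   `"trnF(ttc)"`).
#' @param feature_class One of `"PCG"`, `"tRNA"`, `"rRNA"`,
#'   `"control_region"`.
#' @param start,stop 1-based inclusive positions on the H strand.
#' @param strand `"+"` (H strand) or `"-"` (L strand; the gene is read as the
#'   reverse complement of the annotated span).
#' @return A one-row `data.frame` with columns `name`, `class`, `start`,
#'   `stop`, `strand`.
#' @export
gene_feature <- function(name, feature_class, start, stop, strand) {
  feature_class <- match.arg(feature_class,
                             c("PCG", "tRNA", "rRNA", "control_region"))
  if (!strand %in% c("+", "-")) {
    stop(sprintf("strand must be '+' or '-', got '%s'", strand))
  }
  start <- as.integer(start)
  stop_ <- as.integer(stop)
  if (is.na(start) || is.na(stop_) || start < 1L || stop_ < 1L) {
    stop("start and stop must be positive integers")
  }
  data.frame(name = as.character(name), class = feature_class,
             start = start, stop = stop_, strand = strand,
             stringsAsFactors = FALSE)
}

#' Ordered annotation of a circular mitogenome
#'
#' Bundles a feature table (one row per gene plus, usually, the control
#' region) with the genome length, validating names and coordinates. Features
#' are kept sorted by the start of their non-wrapping span, which is genome
#' order on a circle linearized at the origin.
#'
#' @param features `data.frame` with columns `name`, `class`, `start`,
#'   `stop`, `strand` (rows as produced by [gene_feature()]).
#' @param genome_length Length of the circular genome in bp.
#' @return An object of class `MitogenomeAnnotation` with elements
#'   `features` and `genome_length`.
#' @export
mitogenome_annotation <- function(features, genome_length) {
  genome_length <- as.integer(genome_length)
  stopifnot(is.data.frame(features), genome_length >= 1L)
  need <- c("name", "class", "start", "stop", "strand")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  features <- features[, need]
  features$start <- as.integer(features$start)
  features$stop <- as.integer(features$stop)
  if (anyDuplicated(features$name)) {
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]),
               collapse = ", "))
  }
  bad_class <- setdiff(unique(features$class),
                       c("PCG", "tRNA", "rRNA", "control_region"))
  if (length(bad_class)) {
    stop("unknown feature class: ", paste(bad_class, collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  out_of_range <- features$start < 1L | features$start > genome_length |
    features$stop < 1L | features$stop > genome_length
  if (any(out_of_range)) {
    stop("feature(s) outside [1, genome_length]: ",
         paste(features$name[out_of_range], collapse = ", "))
  }
  ann <- structure(list(features = features, genome_length = genome_length),
                   class = "MitogenomeAnnotation")
  sort_annotation(ann)
}

sort_annotation <- function(ann) {
  ord <- order(ann$features$start)
  ann$features <- ann$features[ord, , drop = FALSE]
  rownames(ann$features) <- NULL
  ann
}

#' @export
print.MitogenomeAnnotation <- function(x, ...) {
  cls <- table(factor(x$features$class,
                      c("PCG", "tRNA", "rRNA", "control_region")))
  cat(sprintf(
    "MitogenomeAnnotation: %d features on a %d bp circular genome\n",
    nrow(x$features), x$genome_length
  ))
  cat(sprintf("  PCG: %d  tRNA: %d  rRNA: %d  control region: %d\n",
              cls[["PCG"]], cls[["tRNA"]], cls[["rRNA"]],
              cls[["control_region"]]))
  invisible(x)
}

#' Length of a feature on a circular genome
#'
#' Non-wrapping features have length `stop - start + 1`; a feature that wraps
#' through the origin (`stop < start`) has length
#' `(L - start + 1) + stop`.
#'
#' @param f One-row feature `data.frame` (see [gene_feature()]).
#' @param L Genome length in bp.
#' @return Feature length in bp.
#' @examples
#' feature_length(gene_feature("cr", "control_region", 15584, 136, "+"), 16541)
#' @export
feature_length <- function(f, L) {
  L <- as.integer(L)
  if (f$stop >= f$start) f$stop - f$start + 1L
  else (L - f$start + 1L) + f$stop
}

## Genome positions covered by a feature, 5'->3' along the H strand span
## (suffix then prefix for wrapping features).
feature_positions <- function(f, L) {
  if (f$stop >= f$start) seq.int(f$start, f$stop)
  else c(seq.int(f$start, L), seq.int(1L, f$stop))
}

#' Extract a feature's sequence from a circular genome
#'
#' Returns the annotated span read off the H strand for `+` features, and its
#' reverse complement for `-` (L-strand) features, so the result is always
#' the coding/structural orientation. Wrapping features concatenate the
#' suffix of the genome with its prefix.
#'
#' @param g A [circular_sequence()].
#' @param f One-row feature `data.frame`.
#' @return DNA string of length [feature_length()].
#' @export
extract_feature_sequence <- function(g, f) {
  stopifnot(inherits(g, "CircularSequence"))
  if (f$start > g$length || f$stop > g$length) {
    stop(sprintf("feature '%s' lies outside the %d bp genome", f$name, g$length))
  }
  s <- if (f$stop >= f$start) {
    substr(g$residues, f$start, f$stop)
  } else {
    paste0(substr(g$residues, f$start, g$length),
           substr(g$residues, 1L, f$stop))
  }
  if (f$strand == "-") revcomp(s) else s
}

#' Read a feature table
#'
#' Tab-separated with header `name  class  start  stop  strand`; thousands
#' separators in coordinates (e.g. `10,032`) are accepted on read and never
#' written.
#'
#' @param path Path to the TSV file.
#' @param genome_length Genome length in bp (coordinates are validated
#'   against it).
#' @return A [mitogenome_annotation()].
#' @export
read_feature_table <- function(path, genome_length) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  need <- c("name", "class", "start", "stop", "strand")
  if (!all(need %in% names(tab))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  strip <- function(x) as.integer(gsub("[, ]", "", x))
  tab$start <- strip(tab$start)
  tab$stop <- strip(tab$stop)
  ## tolerate typographic minus signs from copy-pasted tables
  tab$strand <- chartr("−–", "--", tab$strand)
  mitogenome_annotation(tab[, need], genome_length)
}

#' Write a feature table
#'
#' @param ann A [mitogenome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ann, path) {
  stopifnot(inherits(ann, "MitogenomeAnnotation"))
  write.table(ann$features, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a GenBank flat file as genome plus annotation
#'
#' Thin convenience reader for single-record GenBank flat files: the ORIGIN
#' sequence becomes a [circular_sequence()] and `CDS`, `tRNA`, `rRNA` and
#' `D-loop` features are mapped onto the package's feature classes. Feature
#' names are taken from the `/gene=` qualifier (falling back to `/product=`).
#' Join/complement location syntax is supported for simple one- or
#' two-interval locations; the two-interval case is collapsed to a single
#' wrapping record when it spans the origin.
#'
#' @param path Path to a GenBank flat file.
#' @return List with elements `genome` and `annotation`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  org <- grep("^ORIGIN", lines)
  if (!length(org)) stop("no ORIGIN section in ", path)
  seq_lines <- lines[(org[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  residues <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  id <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[grepl("^LOCUS", lines)][1L])
  g <- circular_sequence(residues, id = id)

  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("no FEATURES section in ", path)
  block <- lines[(feat_start[1L] + 1L):(org[1L] - 1L)]
  is_key <- grepl("^ {5}\\S", block)
  idx <- which(is_key)
  rows <- list()
  for (k in seq_along(idx)) {
    first <- block[idx[k]]
    key <- sub("^ {5}(\\S+).*$", "\\1", first)
    cls <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                  `D-loop` = "control_region", NULL)
    if (is.null(cls)) next
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    body <- paste(gsub("^\\s+", "", block[idx[k]:to]), collapse = " ")
    loc <- sub(paste0("^", key, "\\s+(\\S+).*$"), "\\1", body)
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
    if (length(nums) == 2L) {
      start <- nums[1L]; stop_ <- nums[2L]
    } else if (length(nums) == 4L && nums[2L] == g$length && nums[3L] == 1L) {
      start <- nums[1L]; stop_ <- nums[4L]  # origin-spanning join
    } else {
      warning("skipping feature with unsupported location: ", loc)
      next
    }
    name <- if (grepl('/gene="', body, fixed = TRUE)) {
      sub('^.*?/gene="([^"]+)".*$', "\\1", body)
    } else if (grepl('/product="', body, fixed = TRUE)) {
      sub('^.*?/product="([^"]+)".*$', "\\1", body)
    } else if (cls == "control_region") "control_region" else key
    rows[[length(rows) + 1L]] <- gene_feature(name, cls, start, stop_, strand)
  }
  if (!length(rows)) stop("no usable features in ", path)
  feats <- do.call(rbind, rows)
  ## CDS + gene-level duplicates: keep first occurrence of each name
  feats <- feats[!duplicated(feats$name), , drop = FALSE]
  list(genome = g, annotation = mitogenome_annotation(feats, g$length))
}

## Names of all features covering genome position `pos` (circular-aware).
covering_features <- function(ann, pos) {
  f <- ann$features
  wrap <- f$stop < f$start
  hit <- (!wrap & pos >= f$start & pos <= f$stop) |
    (wrap & (pos >= f$start | pos <= f$stop))
  f$name[hit]
}
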