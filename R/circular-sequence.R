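#' Circular DNA sequence
#'
#' A `CircularSequence` is the genome string of a circular molecule (for a
#' vertebrate mitogenome, typically ~16.5 kb) together with its identifier and
#' explicit length. All circular coordinate arithmetic in the package flows
#' through this type. Residues are stored uppercase over the alphabet
#' `A,C,G,T,N`; `N` marks ambiguous bases.
#'
#' @param residues Single character string of DNA residues. Lowercase input is
#'   uppercased; any character outside `A,C,G,T,N` is an error.
#' @param id Identifier for the molecule.
#' @return An object of class `CircularSequence` with elements `id`,
#'   `residues` and `length`.
#' @examples
#' g <- circular_sequence("acgtn", id = "toy")
#' g$length
#' @export
circular_sequence <- function(residues, id = "genome") {
  stopifnot(is.character(residues), length(residues) == 1L, !is.na(residues))
  residues <- toupper(residues)
  if (nchar(residues) < 1L) {
    stop("a CircularSequence must contain at least one residue")
  }
  bad <- gregexpr("[^ACGTN]", residues)[[1L]]
  if (bad[1L] != -1L) {
    stop(sprintf(
      "illegal residue '%s' at position %d (allowed: A, C, G, T, N)",
      substr(residues, bad[1L], bad[1L]), bad[1L]
    ))
  }
  structure(
    list(id = as.character(id), residues = residues, length = nchar(residues)),
    class = "CircularSequence"
  )
}

#' @export
print.CircularSequence <- function(x, ...) {
  cat(sprintf(
    "CircularSequence '%s': %d bp (circular)\n  %s...\n",
    x$id, x$length, substr(x$residues, 1L, min(60L, x$length))
  ))
  invisible(x)
}

#' @export
length.CircularSequence <- function(x) x$length

#' Reverse complement of a DNA string
#'
#' @param x Character string over `A,C,G,T,N`.
#' @return The reverse complement, same alphabet. `N` maps to `N`.
#' @examples
#' revcomp("AACGT")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Read a single-record FASTA file as a circular sequence
#'
#' Exactly one record is required; the sequence is uppercased on read.
#'
#' @param path Path to a FASTA file.
#' @return A [circular_sequence()].
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop(sprintf("expected exactly 1 FASTA record, found %d in %s",
                 length(set), path))
  }
  circular_sequence(as.character(set[[1L]]),
                    id = sub("\\s.*$", "", names(set)[1L]))
}

#' Write a circular sequence to FASTA
#'
#' One record, 70-column line wrapping.
#'
#' @param g A [circular_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path) {
  stopifnot(inherits(g, "CircularSequence"))
  set <- Biostrings::DNAStringSet(g$residues)
  names(set) <- g$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Rotate a circular genome so it starts at an anchor sequence
#'
#' Circular genomes deposited with different linearization origins must share
#' an origin before global alignment. `rotate_to_anchor` searches for `anchor`
#' on the forward strand and, failing that, on the reverse strand (in which
#' case the genome is reverse-complemented first). The anchor must occur
#' exactly once; the returned genome starts at the anchor's first base.
#'
#' @param g A [circular_sequence()].
#' @param anchor DNA string occurring exactly once in `g` (either strand).
#' @param ann Optional [mitogenome_annotation()] to shift consistently.
#' @return If `ann` is `NULL`, the rotated `CircularSequence`; otherwise a
#'   list with elements `genome` and `annotation`.
#' @export
rotate_to_anchor <- function(g, anchor, ann = NULL) {
  stopifnot(inherits(g, "CircularSequence"))
  anchor <- toupper(anchor)
  if (nchar(anchor) < 1L || nchar(anchor) > g$length) {
    stop("anchor must be a non-empty string no longer than the genome")
  }
  hits <- circular_matches(g$residues, anchor)
  flipped <- FALSE
  if (length(hits) == 0L) {
    rc <- circular_sequence(revcomp(g$residues), id = g$id)
    hits <- circular_matches(rc$residues, anchor)
    if (length(hits) == 0L) {
      stop("anchor not found on either strand")
    }
    g <- rc
    flipped <- TRUE
    if (!is.null(ann)) ann <- flip_annotation(ann)
  }
  if (length(hits) > 1L) {
    stop(sprintf("anchor occurs %d times (positions %s); it must be unique",
                 length(hits), paste(hits, collapse = ", ")))
  }
  out <- rotate_genome(g, hits[1L])
  if (is.null(ann)) return(out)
  list(genome = out, annotation = rotate_annotation(ann, hits[1L]),
       reverse_complemented = flipped)
}

## Start positions (1-based) of `pattern` in circular `seq`.
circular_matches <- function(seq, pattern) {
  L <- nchar(seq)
  k <- nchar(pattern)
  ext <- paste0(seq, substr(seq, 1L, min(k - 1L, L)))
  hits <- gregexpr(pattern, ext, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits[hits <= L])
}

## Rotate so that position `origin` becomes position 1.
rotate_genome <- function(g, origin) {
  if (origin == 1L) return(g)
  s <- paste0(substr(g$residues, origin, g$length),
              substr(g$residues, 1L, origin - 1L))
  circular_sequence(s, id = g$id)
}

rotate_annotation <- function(ann, origin) {
  shift <- function(p) ((p - origin) %% ann$genome_length) + 1L
  ann$features$start <- shift(ann$features$start)
  ann$features$stop <- shift(ann$features$stop)
  sort_annotation(ann)
}

## Reverse-complement an annotation: coordinates mirror, strands flip.
flip_annotation <- function(ann) {
  L <- ann$genome_length
  new_start <- L - ann$features$stop + 1L
  new_stop <- L - ann$features$start + 1L
  ann$features$start <- new_start
  ann$features$stop <- new_stop
  ann$features$strand <- ifelse(ann$features$strand == "+", "-", "+")
  sort_annotation(ann)
}
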