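# Sequence primitives, coordinate conventions, codon-aware utilities and
# FASTA/TSV input-output shared by all modules.
#
# Coordinates are 0-based half-open on the plus strand of the reference,
# everywhere. Base i of sequence `s` is substr(s, i + 1, i + 1).

DNA_BASES <- c("A", "C", "G", "T")

#' Validate and canonicalise a nucleotide sequence
#'
#' Accepts a character scalar (or a [Biostrings::DNAString]) over the
#' alphabet `ACGTN`, case-insensitive, and returns the canonical uppercase
#' string. Degenerate IUPAC letters other than `N` are rejected: PAM
#' degeneracy is handled by enzyme profiles, not by sequence wildcards.
#'
#' @param x character scalar or `DNAString`.
#' @return uppercase character scalar.
#' @export
#' @examples
#' dna("gaattc")
dna <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "DNAStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    ssodn_error("sequence must be a single character string", "ssodn_alphabet_error")
  }
  x <- toupper(x)
  if (!grepl("^[ACGTN]*$", x)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", x), "")[[1]])
    ssodn_error(
      sprintf("sequence contains non-ACGTN character(s): %s",
              paste(bad, collapse = ", ")),
      "ssodn_alphabet_error"
    )
  }
  x
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. Vectorised over a
#' character vector.
#'
#' @param x character vector of ACGTN sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("GAATTC")  # EcoRI site is its own reverse complement
revcomp <- function(x) {
  x <- vapply(x, dna, character(1), USE.NAMES = FALSE)
  out <- as.character(reverseComplement(DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# 0-based half-open substring
seq_sub <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

seq_base <- function(s, i) substr(s, i + 1L, i + 1L)

# Replace [start, end) with `replacement` (plus-strand surgery).
seq_splice <- function(s, start, end, replacement) {
  paste0(seq_sub(s, 0L, start), replacement, seq_sub(s, end, nchar(s)))
}

# FASTA I/O -------------------------------------------------------------

#' Read loci from a FASTA file
#'
#' One locus per record. Returns a named character vector of uppercase
#' ACGTN sequences.
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_locus_fasta <- function(path) {
  set <- readDNAStringSet(path)
  out <- vapply(as.character(set), dna, character(1), USE.NAMES = FALSE)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' Multi-record writer, wrapping at 80 columns.
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- DNAStringSet(unname(x))
  names(set) <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
  writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

# Edit specification -----------------------------------------------------

#' Specify an HDR edit
#'
#' An edit replaces the reference interval `[start, end)` with
#' `replacement`. Insertions have `start == end` and a non-empty
#' replacement; deletions have an empty replacement.
#'
#' @param start,end 0-based half-open interval on the reference.
#' @param replacement replacement sequence (may be `""`).
#' @param label optional label.
#' @return an `edit_spec` object.
#' @export
#' @examples
#' edit_spec(100, 100, "GAATTC", "EcoRI-insert")
edit_spec <- function(start, end, replacement = "", label = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start) {
    ssodn_error("edit interval must satisfy 0 <= start <= end", "ssodn_bounds_error")
  }
  replacement <- dna(replacement)
  structure(
    list(start = start, end = end, replacement = replacement,
         label = label %||% sprintf("edit_%d_%d", start, end)),
    class = "edit_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edit_length_delta <- function(edit) nchar(edit$replacement) - (edit$end - edit$start)

check_edit_bounds <- function(edit, ref) {
  if (edit$end > nchar(ref)) {
    ssodn_error("edit interval exceeds reference bounds", "ssodn_bounds_error")
  }
  invisible(edit)
}

#' @export
print.edit_spec <- function(x, ...) {
  kind <- if (x$start == x$end) "insertion"
          else if (nchar(x$replacement) == 0L) "deletion"
          else "replacement"
  cat(sprintf("<edit_spec> %s: [%d,%d) -> \"%s\" (%s)\n",
              x$label, x$start, x$end, x$replacement, kind))
  invisible(x)
}

# Coding annotation -------------------------------------------------------

#' Coding annotation for a locus
#'
#' CDS intervals (0-based half-open, sorted, non-overlapping) on the
#' reference, the coding strand, and the frame offset (0-2) of the first
#' interval in transcription order.
#'
#' @param intervals data.frame (or 2-column matrix) with columns
#'   `start`, `end`.
#' @param strand `"+"` or `"-"`.
#' @param frame_offset 0, 1 or 2: number of bases of the first codon that
#'   lie upstream of the annotated span.
#' @return a `coding_annotation` object.
#' @export
coding_annotation <- function(intervals, strand = "+", frame_offset = 0L) {
  intervals <- as.data.frame(intervals)
  if (ncol(intervals) < 2L) ssodn_error("intervals need start and end columns", "ssodn_bounds_error")
  names(intervals)[1:2] <- c("start", "end")
  intervals <- intervals[order(intervals$start), 1:2, drop = FALSE]
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  if (any(intervals$end <= intervals$start) || any(intervals$start < 0L)) {
    ssodn_error("CDS intervals must be non-empty and non-negative", "ssodn_bounds_error")
  }
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] < intervals$end[-nrow(intervals)])) {
    ssodn_error("CDS intervals must be non-overlapping", "ssodn_bounds_error")
  }
  if (!strand %in% c("+", "-")) ssodn_error("strand must be '+' or '-'", "ssodn_bounds_error")
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) ssodn_error("frame_offset must be 0..2", "ssodn_bounds_error")
  structure(list(intervals = intervals, strand = strand,
                 frame_offset = frame_offset),
            class = "coding_annotation")
}

#' Read a coding annotation from a BED-like TSV or a minimal GFF3 subset
#'
#' The BED-like format has 6 columns: chrom, start, end, name, frame,
#' strand (start/end already 0-based half-open). The GFF3 subset keeps
#' rows with type `CDS` (1-based closed coordinates, columns 4/5; strand
#' column 7; phase column 8).
#'
#' @param path file path.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return a [coding_annotation()].
#' @export
read_coding_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    tab <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(tab) < 6L) ssodn_error("BED-like annotation needs 6 columns", "ssodn_bounds_error")
    coding_annotation(data.frame(start = tab[[2]], end = tab[[3]]),
                      strand = tab[[6]][1L],
                      frame_offset = as.integer(tab[[5]][1L]))
  } else {
    tab <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    tab <- tab[tab[[3]] == "CDS", , drop = FALSE]
    if (nrow(tab) == 0L) ssodn_error("no CDS rows in GFF3 input", "ssodn_bounds_error")
    strand <- tab[[7]][1L]
    ord <- order(tab[[4]])
    tab <- tab[ord, , drop = FALSE]
    first <- if (strand == "+") 1L else nrow(tab)
    phase <- suppressWarnings(as.integer(tab[[8]][first]))
    coding_annotation(data.frame(start = tab[[4]] - 1L, end = tab[[5]]),
                      strand = strand,
                      frame_offset = if (is.na(phase)) 0L else phase)
  }
}

#' Write a coding annotation as a 6-column BED-like TSV
#'
#' @param annotation a [coding_annotation()].
#' @param path output path.
#' @param chrom,name chrom and name fields for the emitted rows.
#' @return `path`, invisibly.
#' @export
write_coding_annotation <- function(annotation, path, chrom = "locus",
                                    name = "CDS") {
  tab <- data.frame(chrom = chrom,
                    start = annotation$intervals$start,
                    end = annotation$intervals$end,
                    name = name,
                    frame = annotation$frame_offset,
                    strand = annotation$strand)
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Reference coordinates covered by the CDS, in transcription order, as a
# plain integer vector. The frame offset trims leading bases that belong
# to an upstream, uncovered codon.
cds_coords <- function(annotation) {
  iv <- annotation$intervals
  coords <- unlist(lapply(seq_len(nrow(iv)),
                          function(i) seq.int(iv$start[i], iv$end[i] - 1L)),
                   use.names = FALSE)
  if (annotation$strand == "-") coords <- rev(coords)
  if (annotation$frame_offset > 0L) coords <- coords[-seq_len(annotation$frame_offset)]
  coords
}

in_cds <- function(annotation, pos) {
  if (is.null(annotation)) return(FALSE)
  any(pos >= annotation$intervals$start & pos < annotation$intervals$end)
}

complement_base <- function(b) chartr("ACGTN", "TGCAN", b)

# Codon containing reference position `pos`: list(coords, slot) in
# transcription order, or NULL when the position is not covered by a
# complete codon.
codon_at <- function(annotation, pos) {
  coords <- cds_coords(annotation)
  idx <- match(pos, coords)
  if (is.na(idx)) return(NULL)
  codon <- (idx - 1L) %/% 3L
  lo <- codon * 3L + 1L
  hi <- lo + 2L
  if (hi > length(coords)) return(NULL)  # trailing partial codon
  list(coords = coords[lo:hi], slot = idx - lo + 1L)
}

codon_string <- function(ref, annotation, coords) {
  bases <- vapply(coords, function(i) seq_base(ref, i), character(1))
  if (annotation$strand == "-") bases <- complement_base(bases)
  paste0(bases, collapse = "")
}

translate_codon <- function(codon) {
  if (grepl("N", codon)) return(NA_character_)
  unname(GENETIC_CODE[codon])
}

#' Is a single-base substitution synonymous?
#'
#' Positions outside the CDS (or when `annotation` is `NULL`) are trivially
#' compatible with the protein and return `TRUE` with attribute
#' `non_coding = TRUE`. Within the CDS, the affected codon is translated
#' with the standard genetic code before and after the substitution.
#' Positions covered only by a partial codon (frame offset or a truncated
#' trailing codon) are conservatively reported as non-synonymous.
#'
#' @param ref reference sequence (plus strand).
#' @param annotation a [coding_annotation()] or `NULL`.
#' @param position 0-based reference position.
#' @param alt alternate base (plus-strand sense).
#' @return logical scalar with attribute `non_coding`.
#' @export
is_synonymous <- function(ref, annotation, position, alt) {
  ref <- dna(ref)
  position <- as.integer(position)
  if (position < 0L || position >= nchar(ref)) {
    ssodn_error("position out of reference bounds", "ssodn_bounds_error")
  }
  alt <- dna(alt)
  if (!alt %in% DNA_BASES) ssodn_error("alternate base must be A/C/G/T", "ssodn_alphabet_error")
  if (is.null(annotation) || !in_cds(annotation, position)) {
    return(structure(TRUE, non_coding = TRUE))
  }
  cdn <- codon_at(annotation, position)
  if (is.null(cdn)) return(structure(FALSE, non_coding = FALSE))
  before <- codon_string(ref, annotation, cdn$coords)
  alt_tx <- if (annotation$strand == "-") complement_base(alt) else alt
  after <- before
  substr(after, cdn$slot, cdn$slot) <- alt_tx
  aa_before <- translate_codon(before)
  aa_after <- translate_codon(after)
  same <- !is.na(aa_before) && !is.na(aa_after) && aa_before == aa_after
  structure(same, non_coding = FALSE)
}

#' Enumerate synonymous single-base substitutions in an interval
#'
#' Every substitution inside `[start, end)` for which [is_synonymous()] is
#' true, in deterministic order (position ascending, base A < C < G < T).
#' Non-coding positions yield all three alternates, flagged `non_coding`.
#'
#' @param ref reference sequence.
#' @param annotation a [coding_annotation()] or `NULL`.
#' @param start,end 0-based half-open interval.
#' @return data.frame with columns `position`, `ref`, `alt`, `non_coding`.
#' @export
enumerate_synonymous_options <- function(ref, annotation, start, end) {
  ref <- dna(ref)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end > nchar(ref) || end < start) {
    ssodn_error("interval out of reference bounds", "ssodn_bounds_error")
  }
  rows <- list()
  for (pos in seq.int(start, length.out = max(0L, end - start))) {
    refb <- seq_base(ref, pos)
    for (alt in DNA_BASES) {
      if (alt == refb) next
      ok <- is_synonymous(ref, annotation, pos, alt)
      if (isTRUE(as.logical(ok))) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = pos, ref = refb, alt = alt,
          non_coding = isTRUE(attr(ok, "non_coding")),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), non_coding = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Translate the annotated CDS of a locus
#'
#' Utility used to verify that auxiliary donor mutations preserve the
#' wild-type protein. Trailing partial codons are dropped.
#'
#' @param ref reference sequence.
#' @param annotation a [coding_annotation()].
#' @return single-letter amino-acid string.
#' @export
translate_cds <- function(ref, annotation) {
  ref <- dna(ref)
  coords <- cds_coords(annotation)
  n <- (length(coords) %/% 3L) * 3L
  if (n == 0L) return("")
  coords <- coords[seq_len(n)]
  bases <- vapply(coords, function(i) seq_base(ref, i), character(1))
  if (annotation$strand == "-") bases <- complement_base(bases)
  codons <- vapply(split(bases, rep(seq_len(n / 3L), each = 3L)),
                   paste0, character(1), collapse = "")
  paste0(vapply(codons, translate_codon, character(1)), collapse = "")
}
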