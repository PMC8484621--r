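# Quantify editing outcomes from amplicon reads: global affine-gap
# alignment against both the wild-type and HDR alleles, indel calling in
# enzyme-specific windows, per-read classification into WT / NHEJ /
# perfect HDR / imperfect HDR, and the restriction-digest HDR fraction.

map_through_edit <- function(x, edit) {
  delta <- edit_length_delta(edit)
  ifelse(x <= edit$start, x, ifelse(x >= edit$end, x + delta, edit$start))
}

# Enzyme-specific classification window on the wild-type reference:
# Cas9: 8 bp centred on the blunt cut ([cut-4, cut+4)).
# Cas12a: 9 bp starting 3 bp PAM-proximal of the PAM-distal (23-nt) cut,
# extending PAM-distal.
classification_window <- function(guide) {
  g <- as_guide_row(guide)
  if (g$enzyme == "Cas12a") {
    if (g$strand == "+") c(g$cut_t - 3L, g$cut_t + 6L)
    else c(g$cut_t - 6L, g$cut_t + 3L)
  } else {
    c(g$cut - 4L, g$cut + 4L)
  }
}

#' Amplicon model for read classification
#'
#' Holds the wild-type amplicon, the HDR allele (wild type with the full
#' donor-encoded allele applied: the edit plus every auxiliary mutation),
#' the guide, and the enzyme-specific classification window on both
#' coordinate systems.
#'
#' @param ref wild-type amplicon sequence.
#' @param guide one row of a [find_guides()] table.
#' @param edit an [edit_spec()].
#' @param mutations a [mutation_set()] of donor auxiliary mutations.
#' @param window optional override of the wild-type-coordinate window
#'   (length-2 integer, 0-based half-open).
#' @return an `amplicon_model` object.
#' @export
amplicon_model <- function(ref, guide, edit, mutations = mutation_set(),
                           window = NULL) {
  ref <- dna(ref)
  check_edit_bounds(edit, ref)
  g <- as_guide_row(guide)
  hdr <- ref
  for (i in seq_len(nrow(mutations))) {
    rc <- mutations$ref_coord[i]
    substr(hdr, rc + 1L, rc + 1L) <- mutations$alt[i]
  }
  hdr <- seq_splice(hdr, edit$start, edit$end, edit$replacement)
  win_wt <- as.integer(window %||% classification_window(g))
  win_hdr <- c(map_through_edit(win_wt[1], edit),
               if (win_wt[2] >= edit$end) win_wt[2] + edit_length_delta(edit)
               else win_wt[2])
  mut_hdr <- if (nrow(mutations)) map_through_edit(mutations$ref_coord, edit)
             else integer(0)
  cuts <- cut_positions(g)
  structure(list(
    wt = ref, hdr = hdr, guide = g, edit = edit, mutations = mutations,
    window_wt = win_wt, window_hdr = as.integer(win_hdr),
    special_hdr = as.integer(mut_hdr),
    edit_region_hdr = c(edit$start, edit$start + nchar(edit$replacement)),
    cut_wt = as.integer(cuts[1]),
    cut_hdr = as.integer(map_through_edit(cuts[1], edit))
  ), class = "amplicon_model")
}

# Parse a pair of equal-length gapped strings (pattern = read, subject =
# reference) into events in 0-based reference coordinates:
#   mismatch: positions; del: intervals [start, end) deleted from the
#   read; ins: boundary position, length and inserted sequence.
alignment_events <- function(pattern, subject) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  sc <- strsplit(subject, "", fixed = TRUE)[[1]]
  is_ins <- sc == "-"
  is_del <- pc == "-"
  consumed <- cumsum(!is_ins)           # ref bases consumed through column i
  ref_of <- consumed - 1L               # 0-based ref coord of a non-ins column
  mism <- ref_of[!is_ins & !is_del & pc != sc]
  r <- rle(is_del)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  del <- NULL
  for (k in which(r$values)) {
    del <- rbind(del, c(ref_of[starts[k]], ref_of[ends[k]] + 1L))
  }
  r2 <- rle(is_ins)
  ends2 <- cumsum(r2$lengths); starts2 <- ends2 - r2$lengths + 1L
  ins <- list()
  for (k in which(r2$values)) {
    ins[[length(ins) + 1L]] <- list(
      pos = consumed[starts2[k]],       # boundary before the next ref base
      len = r2$lengths[k],
      seq = paste0(pc[starts2[k]:ends2[k]], collapse = ""))
  }
  list(mismatch = as.integer(mism),
       del = if (is.null(del)) matrix(integer(0), ncol = 2) else del,
       ins = ins)
}

# Same events, computed from the C-level PairwiseAlignments accessors
# (mismatchTable / indel) for the whole batch at once. Coordinate
# systems (verified empirically against the gapped-string walker):
# insertion() ranges locate each insertion in SUBJECT coordinates
# (start - 1 is the 0-based reference boundary), deletion() ranges in
# PATTERN coordinates, and mismatchTable()$SubjectStart is subject
# coordinates. Deletions are mapped to the reference by merging the two
# event streams along the alignment while tracking cumulative gap
# widths. Returns a list of per-read event lists; alignment_events() is
# the slow reference for this conversion.
batch_alignment_events <- function(aln, reads) {
  n <- length(reads)
  mmt <- Biostrings::mismatchTable(aln)
  mm_by <- split(mmt$SubjectStart - 1L, factor(mmt$PatternId, levels = seq_len(n)))
  idl <- Biostrings::indel(aln)
  ins_df <- as.data.frame(Biostrings::insertion(idl))
  del_df <- as.data.frame(Biostrings::deletion(idl))
  ins_by <- split(ins_df, factor(ins_df$group, levels = seq_len(n)))
  del_by <- split(del_df, factor(del_df$group, levels = seq_len(n)))
  lapply(seq_len(n), function(i) {
    ii <- ins_by[[i]]; di <- del_by[[i]]
    del <- matrix(integer(0), ncol = 2)
    ins <- list()
    ki <- 1L; kd <- 1L
    cum_ins <- 0L; cum_del <- 0L
    while (ki <= nrow(ii) || kd <= nrow(di)) {
      ins_subj <- if (ki <= nrow(ii)) ii$start[ki] - 1L else Inf
      del_subj <- if (kd <= nrow(di)) di$start[kd] - 1L - cum_ins + cum_del
                  else Inf
      if (ins_subj <= del_subj) {
        rs <- ins_subj + cum_ins - cum_del + 1L  # 1-based read coord
        ins[[length(ins) + 1L]] <- list(
          pos = as.integer(ins_subj),
          len = ii$width[ki],
          seq = substring(reads[i], rs, rs + ii$width[ki] - 1L))
        cum_ins <- cum_ins + ii$width[ki]
        ki <- ki + 1L
      } else {
        a <- as.integer(del_subj)
        del <- rbind(del, c(a, a + di$width[kd]))
        cum_del <- cum_del + di$width[kd]
        kd <- kd + 1L
      }
    }
    list(mismatch = as.integer(sort(mm_by[[i]])), del = del, ins = ins)
  })
}

# Score-preserving rotations of a single insertion (boundary p, inserted
# sequence s) one step left/right within its repeat context.
ins_shift_left <- function(ref, p, s) {
  if (p > 0L && seq_base(ref, p - 1L) == substr(s, nchar(s), nchar(s))) {
    list(p = p - 1L,
         s = paste0(substr(s, nchar(s), nchar(s)), substr(s, 1L, nchar(s) - 1L)))
  } else NULL
}
ins_shift_right <- function(ref, p, s) {
  if (p < nchar(ref) && seq_base(ref, p) == substr(s, 1L, 1L)) {
    list(p = p + 1L, s = paste0(substr(s, 2L, nchar(s)), substr(s, 1L, 1L)))
  } else NULL
}

# Score-preserving canonicalisation: slide each indel within its repeat
# context toward the predicted cut so that equal-score placements are
# resolved in favour of the cut site. `barrier` (an interval) is never
# entered: insertions stop at its edges, deletions stop short of
# overlapping it.
normalize_events <- function(events, ref, cut, barrier = NULL) {
  n <- nchar(ref)
  ins_ok <- function(p) is.null(barrier) || p <= barrier[1] || p >= barrier[2]
  del_ok <- function(a, b) is.null(barrier) || b <= barrier[1] || a >= barrier[2]
  for (i in seq_along(events$ins)) {
    e <- events$ins[[i]]
    p <- e$pos; s <- e$seq
    repeat {
      step <- if (p > cut) ins_shift_left(ref, p, s)
              else if (p < cut) ins_shift_right(ref, p, s)
              else NULL
      if (is.null(step) || !ins_ok(step$p)) break
      p <- step$p; s <- step$s
    }
    events$ins[[i]]$pos <- p
    events$ins[[i]]$seq <- s
  }
  if (nrow(events$del)) {
    for (i in seq_len(nrow(events$del))) {
      a <- events$del[i, 1]; b <- events$del[i, 2]
      repeat {
        if (b < cut && b < n && seq_base(ref, a) == seq_base(ref, b) &&
            del_ok(a + 1L, b + 1L)) {
          a <- a + 1L; b <- b + 1L
        } else if (a > cut && a > 0L &&
                   seq_base(ref, a - 1L) == seq_base(ref, b - 1L) &&
                   del_ok(a - 1L, b - 1L)) {
          a <- a - 1L; b <- b - 1L
        } else break
      }
      events$del[i, ] <- c(a, b)
    }
  }
  events
}

# Try to rotate every indel out of `region` (the donor-encoded
# replacement). Returns the adjusted events plus `ok = FALSE` when some
# indel (or mismatch) necessarily damages the region.
escape_region <- function(events, ref, region) {
  r1 <- region[1]; r2 <- region[2]
  if (any(events$mismatch >= r1 & events$mismatch < r2)) {
    return(list(events = events, ok = FALSE))
  }
  for (i in seq_along(events$ins)) {
    e <- events$ins[[i]]
    if (e$pos <= r1 || e$pos >= r2) next
    p <- e$pos; s <- e$seq; moved <- NULL
    while (p < r2) {
      step <- ins_shift_right(ref, p, s)
      if (is.null(step)) break
      p <- step$p; s <- step$s
    }
    if (p >= r2) moved <- list(p = p, s = s)
    if (is.null(moved)) {
      p <- e$pos; s <- e$seq
      while (p > r1) {
        step <- ins_shift_left(ref, p, s)
        if (is.null(step)) break
        p <- step$p; s <- step$s
      }
      if (p <= r1) moved <- list(p = p, s = s)
    }
    if (is.null(moved)) return(list(events = events, ok = FALSE))
    events$ins[[i]]$pos <- moved$p
    events$ins[[i]]$seq <- moved$s
  }
  if (nrow(events$del)) {
    n <- nchar(ref)
    for (i in seq_len(nrow(events$del))) {
      a <- events$del[i, 1]; b <- events$del[i, 2]
      if (b <= r1 || a >= r2) next
      a2 <- a; b2 <- b; moved <- NULL
      while (a2 < r2 && b2 < n &&
             seq_base(ref, a2) == seq_base(ref, b2)) {
        a2 <- a2 + 1L; b2 <- b2 + 1L
      }
      if (a2 >= r2) moved <- c(a2, b2)
      if (is.null(moved)) {
        a2 <- a; b2 <- b
        while (b2 > r1 && a2 > 0L &&
               seq_base(ref, a2 - 1L) == seq_base(ref, b2 - 1L)) {
          a2 <- a2 - 1L; b2 <- b2 - 1L
        }
        if (b2 <= r1) moved <- c(a2, b2)
      }
      if (is.null(moved)) return(list(events = events, ok = FALSE))
      events$del[i, ] <- moved
    }
  }
  list(events = events, ok = TRUE)
}

# Indel-window intersection: a deletion intersects [a, b) when the
# intervals overlap; an insertion when its boundary lies in [a, b]
# (an insertion at either edge separates a window base from its
# neighbour).
indel_in_window <- function(events, window) {
  a <- window[1]; b <- window[2]
  if (nrow(events$del) &&
      any(events$del[, 1] < b & events$del[, 2] > a)) return(TRUE)
  if (length(events$ins) &&
      any(vapply(events$ins, function(e) e$pos >= a && e$pos <= b,
                 logical(1)))) return(TRUE)
  FALSE
}

n_indels <- function(events) nrow(events$del) + length(events$ins)

#' Read amplicon reads from FASTQ or FASTA
#'
#' @param path file path; `.fastq`/`.fq` (optionally `.gz`) is read as
#'   FASTQ, anything else as FASTA. Qualities are ignored.
#' @return named character vector of reads.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  set <- readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Align and classify amplicon reads
#'
#' Each read is globally aligned (affine gaps) against both the wild-type
#' and the HDR allele; the higher-scoring hypothesis is retained (ties go
#' to wild type). Calls: `perfect_HDR` for HDR-hypothesis reads with no
#' mismatch or indel across the classification window and the donor
#' mutation positions; `imperfect_HDR` for HDR-hypothesis reads with an
#' additional indel intersecting the window; `NHEJ` for wild-type
#' hypothesis reads with an indel intersecting the window; `WT`
#' otherwise (substitution-only sequencing noise outside donor positions
#' does not flip calls). Reads under `min_identity` percent identity to
#' both alleles are `unassigned` and excluded from denominators. On
#' equal-score placements, indels are normalised toward the predicted cut
#' site before windows are tested.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads, each
#'   at least 40 nt.
#' @param model an [amplicon_model()].
#' @param scoring alignment scores: `match`, `mismatch`, `gap_open`,
#'   `gap_ext` (defaults 2 / -3 / 5 / 1).
#' @param min_identity identity threshold (percent) below which a read is
#'   unassigned.
#' @return data.frame with one row per read: `id`, `call`, `hypothesis`,
#'   `n_indel`, `n_mismatch`.
#' @export
classify_reads <- function(reads, model,
                           scoring = list(match = 2, mismatch = -3,
                                          gap_open = 5, gap_ext = 1),
                           min_identity = 50) {
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  if (length(reads) == 0L) {
    ssodn_error("no reads supplied", "ssodn_empty_error")
  }
  if (any(nchar(reads) < 40L)) {
    ssodn_error("reads must be at least 40 nt", "ssodn_bounds_error")
  }
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  pats <- DNAStringSet(unname(reads))
  submat <- nucleotideSubstitutionMatrix(match = scoring$match,
                                         mismatch = scoring$mismatch,
                                         baseOnly = FALSE)
  aln_wt <- pairwiseAlignment(pats, DNAString(model$wt), type = "global",
                              substitutionMatrix = submat,
                              gapOpening = scoring$gap_open,
                              gapExtension = scoring$gap_ext)
  aln_hdr <- pairwiseAlignment(pats, DNAString(model$hdr), type = "global",
                               substitutionMatrix = submat,
                               gapOpening = scoring$gap_open,
                               gapExtension = scoring$gap_ext)
  use_hdr <- methods::slot(aln_hdr, "score") > methods::slot(aln_wt, "score")
  low_id <- pid(aln_wt) < min_identity & pid(aln_hdr) < min_identity
  ev_wt_all <- batch_alignment_events(aln_wt, unname(reads))
  ev_hdr_all <- batch_alignment_events(aln_hdr, unname(reads))

  calls <- character(length(reads))
  hypo <- character(length(reads))
  n_indel <- integer(length(reads))
  n_mm <- integer(length(reads))
  er <- model$edit_region_hdr
  for (i in seq_along(reads)) {
    if (low_id[i]) {
      calls[i] <- "unassigned"
      hypo[i] <- NA_character_
      next
    }
    as_wt <- !use_hdr[i]
    if (use_hdr[i]) {
      # the donor-encoded allele must actually be present: an indel that
      # cannot be rotated out of the replacement region (or a mismatch
      # inside it) refutes the HDR hypothesis
      esc <- escape_region(ev_hdr_all[[i]], model$hdr, er)
      if (!esc$ok) {
        as_wt <- TRUE
      } else {
        ev <- normalize_events(esc$events, model$hdr, model$cut_hdr,
                               barrier = er)
        hypo[i] <- "hdr"
        n_indel[i] <- n_indels(ev)
        n_mm[i] <- length(ev$mismatch)
        win <- model$window_hdr
        special <- model$special_hdr
        if (indel_in_window(ev, win)) {
          calls[i] <- "imperfect_HDR"
        } else {
          mm_hit <- any(ev$mismatch >= win[1] & ev$mismatch < win[2]) ||
            any(ev$mismatch %in% special)
          del_hit <- nrow(ev$del) > 0 && any(
            apply(ev$del, 1, function(d) any(special >= d[1] & special < d[2])))
          calls[i] <- if (!mm_hit && !del_hit) "perfect_HDR" else "WT"
        }
      }
    }
    if (as_wt) {
      ev <- normalize_events(ev_wt_all[[i]], model$wt, model$cut_wt)
      hypo[i] <- "wt"
      n_indel[i] <- n_indels(ev)
      n_mm[i] <- length(ev$mismatch)
      calls[i] <- if (indel_in_window(ev, model$window_wt)) "NHEJ" else "WT"
    }
  }
  data.frame(id = ids, call = calls, hypothesis = hypo,
             n_indel = n_indel, n_mismatch = n_mm,
             stringsAsFactors = FALSE)
}

#' Summarise read calls into editing fractions
#'
#' Percentages are over assigned reads; `total_editing` is the percentage
#' of reads carrying any editing outcome (NHEJ + perfect HDR + imperfect
#' HDR = 100 - WT).
#'
#' @param calls output of [classify_reads()].
#' @return an `editing_summary` list: `n_reads`, `n_unassigned`, `pct`
#'   (named WT / NHEJ / perfect_HDR / imperfect_HDR), `total_editing`.
#' @export
summarize_calls <- function(calls) {
  assigned <- calls[calls$call != "unassigned", , drop = FALSE]
  if (nrow(assigned) == 0L) {
    ssodn_error("no assigned reads to summarise", "ssodn_empty_error")
  }
  lv <- c("WT", "NHEJ", "perfect_HDR", "imperfect_HDR")
  counts <- table(factor(assigned$call, levels = lv))
  pct <- 100 * as.numeric(counts) / nrow(assigned)
  names(pct) <- lv
  structure(list(
    n_reads = nrow(assigned),
    n_unassigned = nrow(calls) - nrow(assigned),
    pct = pct,
    total_editing = 100 - pct[["WT"]]
  ), class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("<editing_summary> %d reads (%d unassigned)\n", x$n_reads,
              x$n_unassigned))
  for (k in names(x$pct)) cat(sprintf("  %-14s %6.2f%%\n", k, x$pct[[k]]))
  cat(sprintf("  %-14s %6.2f%%\n", "total_editing", x$total_editing))
  invisible(x)
}

#' Write an editing summary as TSV and JSON
#'
#' @param summary an `editing_summary`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the two paths, invisibly.
#' @export
write_summary <- function(summary, prefix) {
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  tab <- data.frame(metric = c("n_reads", "n_unassigned", names(summary$pct),
                               "total_editing"),
                    value = c(summary$n_reads, summary$n_unassigned,
                              unname(summary$pct), summary$total_editing))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_json(list(n_reads = summary$n_reads,
                  n_unassigned = summary$n_unassigned,
                  pct = as.list(summary$pct),
                  total_editing = summary$total_editing),
             js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}

#' Restriction-digest HDR fraction
#'
#' Fraction of molecules cut by the diagnostic restriction enzyme:
#' `mean(cut_a, cut_b) / (mean(cut_a, cut_b) + uncut) * 100`, where
#' `cut_a` and `cut_b` are the molar concentrations of the two cut
#' products and `uncut` of the uncut product.
#'
#' @param cut_a,cut_b,uncut molar concentrations, all >= 0, not all zero.
#' @return percent cut.
#' @export
#' @examples
#' digest_fraction(2, 4, 7)  # 30
digest_fraction <- function(cut_a, cut_b, uncut) {
  vals <- c(cut_a, cut_b, uncut)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    ssodn_error("concentrations must be finite and >= 0", "ssodn_domain_error")
  }
  if (all(vals == 0)) {
    ssodn_error("digest fraction undefined for all-zero input", "ssodn_domain_error")
  }
  m <- mean(c(cut_a, cut_b))
  100 * m / (m + uncut)
}
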