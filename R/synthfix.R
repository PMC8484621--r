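# Deterministic generators for toy loci, coding annotations, edits, and
# simulated read sets with known outcome fractions. Everything is
# reproducible from an integer seed through R's own RNG; the same seed
# yields bit-identical outputs.

#' Simulation specification
#'
#' @param seed integer seed; the same seed yields bit-identical outputs.
#' @param locus_length toy locus length (>= 200 nt).
#' @param cas9_pam_plus,cas9_pam_minus plus-strand start coordinates of
#'   planted Cas9 PAMs on the plus / minus strand.
#' @param tttv_pam_plus start coordinates of planted Cas12a TTTV PAMs
#'   (plus strand).
#' @param pair optional planted nickase pair:
#'   `list(left_cut =, spacing =, orientation = "out"|"in")`.
#' @param cds optional planted coding annotation:
#'   `list(start =, end =, strand =, frame =)`.
#' @param n_reads number of simulated reads.
#' @param fractions outcome fractions (sum to 1) named
#'   `wt`, `nhej`, `perfect_hdr`, `imperfect_hdr`.
#' @param indel_mean mean NHEJ indel size (geometric size model,
#'   `1 + Geom(1/indel_mean)`); the size model is synthetic, a stand-in
#'   for real NHEJ spectra.
#' @param ins_prob probability that an NHEJ indel is an insertion.
#' @param sub_rate per-base substitution error rate applied to every
#'   read.
#' @param guard guard band (nt) around planted features kept free of
#'   accidental PAMs so oracle counts are exact.
#' @return a `sim_spec` object.
#' @export
sim_spec <- function(seed = 1L, locus_length = 300L,
                     cas9_pam_plus = integer(0), cas9_pam_minus = integer(0),
                     tttv_pam_plus = integer(0), pair = NULL, cds = NULL,
                     n_reads = 2000L,
                     fractions = c(wt = 0.55, nhej = 0.25,
                                   perfect_hdr = 0.15, imperfect_hdr = 0.05),
                     indel_mean = 3, ins_prob = 0.5, sub_rate = 0.005,
                     guard = 30L) {
  locus_length <- as.integer(locus_length)
  if (locus_length < 200L) ssodn_error("locus_length must be >= 200", "ssodn_spec_error")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    ssodn_error("outcome fractions must be >= 0 and sum to 1", "ssodn_spec_error")
  }
  if (!is.null(pair)) {
    stopifnot(is.list(pair), !is.null(pair$left_cut), !is.null(pair$spacing))
    pair$orientation <- pair$orientation %||% "out"
    if (pair$left_cut + pair$spacing + 23L > locus_length || pair$left_cut < 23L) {
      ssodn_error("planted pair does not fit in the locus", "ssodn_spec_error")
    }
  }
  structure(list(seed = as.integer(seed), locus_length = locus_length,
                 cas9_pam_plus = as.integer(cas9_pam_plus),
                 cas9_pam_minus = as.integer(cas9_pam_minus),
                 tttv_pam_plus = as.integer(tttv_pam_plus),
                 pair = pair, cds = cds,
                 n_reads = as.integer(n_reads), fractions = fractions,
                 indel_mean = indel_mean, ins_prob = ins_prob,
                 sub_rate = sub_rate, guard = as.integer(guard)),
            class = "sim_spec")
}

random_bases <- function(n) paste0(sample(DNA_BASES, n, replace = TRUE),
                                   collapse = "")

set_bases <- function(s, start, bases) {
  substr(s, start + 1L, start + nchar(bases)) <- bases
  s
}

# Remove accidental PAM-forming motifs inside guard windows, leaving the
# planted motif bases untouched. Iterative targeted resampling.
scrub_guard <- function(seq, centers, protected, guard, motifs) {
  n <- nchar(seq)
  for (iter in 1:200) {
    dirty <- FALSE
    for (c0 in centers) {
      # scan a few bases beyond the band so motifs straddling the edge
      # are caught
      lo <- max(0L, c0 - guard - 4L); hi <- min(n, c0 + guard + 4L)
      win <- seq_sub(seq, lo, hi)
      for (m in motifs) {
        hits <- gregexpr(m$pattern, win, perl = TRUE)[[1]]
        if (hits[1] == -1L) next
        for (h in hits) {
          pos <- lo + h - 1L + m$fix_offset   # base to randomise
          if (pos %in% protected) next
          cur <- seq_base(seq, pos)
          repl <- sample(setdiff(m$fix_to, cur), 1L)
          seq <- set_bases(seq, pos, repl)
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(seq)
  }
  ssodn_error("could not scrub guard bands free of accidental PAMs", "ssodn_spec_error")
}

cas9_guard_motifs <- list(
  list(pattern = "(?=GG)", fix_offset = 1L, fix_to = c("A", "T")),
  list(pattern = "(?=CC)", fix_offset = 0L, fix_to = c("A", "T"))
)
cas12a_guard_motifs <- c(cas9_guard_motifs, list(
  list(pattern = "(?=TTT[ACG])", fix_offset = 1L, fix_to = c("A", "C", "G")),
  list(pattern = "(?=[CGT]AAA)", fix_offset = 2L, fix_to = c("C", "G", "T"))
))

#' Generate a toy locus with planted features
#'
#' Random background sequence with Cas9/Cas12a PAMs, an optional PAM-out
#' (or PAM-in) nickase pair, and an optional CDS planted at the requested
#' coordinates. A guard band around every planted feature is scrubbed of
#' accidental PAM motifs so that guide discovery inside the band recovers
#' exactly the planted sites.
#'
#' @param spec a [sim_spec()].
#' @return list: `sequence` (named character), `truth` (data.frame of
#'   planted sites), `annotation` ([coding_annotation()] or `NULL`),
#'   `spec`.
#' @export
make_toy_locus <- function(spec) {
  set.seed(spec$seed)
  n <- spec$locus_length
  seq <- random_bases(n)
  truth <- list()
  protected <- integer(0)
  centers <- integer(0)
  motifs <- cas9_guard_motifs

  plant_cas9 <- function(seq, pam_start, strand) {
    if (strand == "+") {
      if (pam_start < 20L || pam_start + 3L > n) {
        ssodn_error("planted Cas9 PAM does not fit", "ssodn_spec_error")
      }
      seq <- set_bases(seq, pam_start, "AGG")
      truth[[length(truth) + 1L]] <<- data.frame(
        enzyme = "Cas9", strand = "+", pam_start = pam_start,
        cut = pam_start - 3L, stringsAsFactors = FALSE)
      protected <<- c(protected, pam_start + 1:2)
      centers <<- c(centers, pam_start)
    } else {
      if (pam_start < 0L || pam_start + 23L > n) {
        ssodn_error("planted Cas9 PAM does not fit", "ssodn_spec_error")
      }
      seq <- set_bases(seq, pam_start, "CCA")
      truth[[length(truth) + 1L]] <<- data.frame(
        enzyme = "Cas9", strand = "-", pam_start = pam_start,
        cut = pam_start + 6L, stringsAsFactors = FALSE)
      protected <<- c(protected, pam_start + 0:1)
      centers <<- c(centers, pam_start)
    }
    seq
  }

  for (p in spec$cas9_pam_plus) seq <- plant_cas9(seq, p, "+")
  for (p in spec$cas9_pam_minus) seq <- plant_cas9(seq, p, "-")
  for (p in spec$tttv_pam_plus) {
    if (p < 0L || p + 27L > n) ssodn_error("planted TTTV PAM does not fit", "ssodn_spec_error")
    seq <- set_bases(seq, p, "TTTC")
    truth[[length(truth) + 1L]] <- data.frame(
      enzyme = "Cas12a", strand = "+", pam_start = p,
      cut = p + 22L, stringsAsFactors = FALSE)
    protected <- c(protected, p + 0:3)
    centers <- c(centers, p)
    motifs <- cas12a_guard_motifs
  }
  if (!is.null(spec$pair)) {
    lc <- as.integer(spec$pair$left_cut)
    sp <- as.integer(spec$pair$spacing)
    if (identical(spec$pair$orientation, "out")) {
      seq <- plant_cas9(seq, lc - 6L, "-")   # left nick at lc
      seq <- plant_cas9(seq, lc + sp + 3L, "+")  # right nick at lc + sp
    } else {
      seq <- plant_cas9(seq, lc + 3L, "+")   # PAM-in: left nick from + guide
      seq <- plant_cas9(seq, lc + sp - 6L, "-")
    }
    # a stray PAM within pairing range of the planted nicks (or of the
    # inter-nick interval) would create spurious pairs: scrub a corridor
    # wide enough that any accidental partner guide is removed
    corridor <- seq.int(max(spec$guard, lc - 95L),
                        min(n - spec$guard, lc + sp + 95L),
                        by = spec$guard)
    centers <- c(centers, corridor)
  }
  seq <- scrub_guard(seq, centers, protected, spec$guard, motifs)

  annotation <- NULL
  if (!is.null(spec$cds)) {
    annotation <- coding_annotation(
      data.frame(start = spec$cds$start, end = spec$cds$end),
      strand = spec$cds$strand %||% "+",
      frame_offset = spec$cds$frame %||% 0L)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(enzyme = character(), strand = character(),
               pam_start = integer(), cut = integer())
  list(sequence = c(toy_locus = seq), truth = truth,
       annotation = annotation, spec = spec)
}

count_matches <- function(needle, haystack) {
  if (nchar(needle) == 0L) return(0L)
  m <- gregexpr(needle, haystack, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

# One window-intersecting indel. When `protect` (an interval that must
# stay intact, e.g. the donor-encoded replacement) is given, placements
# damaging it are rejected and redrawn. When `avoid` (the donor
# replacement sequence) is given, draws whose junction spells out an
# extra copy of it are rejected: such a read would genuinely carry the
# intended allele and be indistinguishable from HDR.
random_indel <- function(ref, window, indel_mean, ins_prob, protect = NULL,
                         avoid = NULL) {
  a <- window[1]; b <- window[2]
  base_count <- if (is.null(avoid)) 0L else count_matches(avoid, ref)
  for (try in 1:100) {
    size <- 1L + rgeom(1L, 1 / indel_mean)
    if (runif(1) < ins_prob) {
      pos <- sample(seq.int(a + 1L, b - 1L), 1L)
      if (!is.null(protect) && pos > protect[1] && pos < protect[2]) next
      out <- seq_splice(ref, pos, pos, random_bases(size))
    } else {
      lo <- max(1L, a - size + 2L)
      hi <- min(b - 1L, nchar(ref) - size - 1L)
      if (hi < lo) { lo <- a; hi <- a }
      start <- sample(seq.int(lo, hi), 1L)
      end <- min(start + size, nchar(ref))
      if (!is.null(protect) && start < protect[2] && end > protect[1]) next
      out <- seq_splice(ref, start, end, "")
    }
    if (!is.null(avoid) && count_matches(avoid, out) > base_count) next
    return(list(seq = out))
  }
  ssodn_error("could not place a window indel away from the protected interval",
              "ssodn_spec_error")
}

apply_sub_noise <- function(reads, rate) {
  if (rate <= 0) return(reads)
  vapply(reads, function(r) {
    k <- rbinom(1L, nchar(r), rate)
    if (k == 0L) return(r)
    pos <- sample.int(nchar(r), k)
    for (p in pos) {
      cur <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate amplicon reads with known outcome fractions
#'
#' Draws read counts from the multinomial defined by the spec's outcome
#' fractions. WT reads copy the wild-type amplicon; NHEJ reads carry a
#' window-intersecting indel (geometric size, insertion or deletion);
#' perfect-HDR reads copy the HDR allele; imperfect-HDR reads carry the
#' HDR allele plus an extra window indel. Uniform substitution noise is
#' applied to every read.
#'
#' @param model an [amplicon_model()].
#' @param spec a [sim_spec()].
#' @return list: `reads` (named character vector) and `truth`
#'   (data.frame `id`, `class`).
#' @export
simulate_reads <- function(model, spec) {
  set.seed(spec$seed)
  counts <- as.vector(rmultinom(1L, spec$n_reads, spec$fractions))
  names(counts) <- names(spec$fractions)
  reads <- character(0); classes <- character(0)
  add <- function(n, cls, maker) {
    if (n == 0L) return()
    new <- vapply(seq_len(n), function(i) maker(), character(1))
    reads <<- c(reads, new)
    classes <<- c(classes, rep(cls, n))
  }
  add(counts[["wt"]], "WT", function() model$wt)
  add(counts[["nhej"]], "NHEJ", function()
    random_indel(model$wt, model$window_wt, spec$indel_mean, spec$ins_prob,
                 avoid = model$edit$replacement)$seq)
  add(counts[["perfect_hdr"]], "perfect_HDR", function() model$hdr)
  add(counts[["imperfect_hdr"]], "imperfect_HDR", function()
    random_indel(model$hdr, model$window_hdr, spec$indel_mean, spec$ins_prob,
                 protect = model$edit_region_hdr)$seq)
  reads <- apply_sub_noise(reads, spec$sub_rate)
  ids <- sprintf("read%05d_%s", seq_along(reads), classes)
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(id = ids, class = classes, stringsAsFactors = FALSE))
}

#' Write simulated reads as FASTQ
#'
#' Constant quality (`I`); the classifier ignores qualities.
#'
#' @param reads named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- DNAStringSet(unname(reads))
  names(set) <- names(reads)
  quals <- BStringSet(vapply(nchar(reads), function(w)
    strrep("I", w), character(1)))
  writeXStringSet(set, filepath = path, format = "fastq", qualities = quals)
  invisible(path)
}
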