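# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's own code paths: the PAM scan is a
# character-level sliding window, translation goes through
# Biostrings::translate, and window intersection is a literal interval
# check.

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# Sliding-window IUPAC match on the plus strand: 0-based start coords.
oracle_iupac_scan <- function(seq, pattern) {
  pl <- strsplit(pattern, "")[[1]]
  sl <- strsplit(seq, "")[[1]]
  k <- length(pl)
  out <- integer(0)
  if (length(sl) < k) return(out)
  for (i in 0:(length(sl) - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!sl[i + j] %in% IUPAC_SETS[[pl[j]]]) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i)
  }
  out
}

# Brute-force guide enumeration mirroring the documented geometry, built
# on the sliding-window scan only.
oracle_find_guides_cas9 <- function(seq) {
  n <- nchar(seq)
  plus <- oracle_iupac_scan(seq, "NGG")
  plus <- plus[plus >= 20 & plus + 3 <= n]
  minus <- oracle_iupac_scan(seq, "CCN")
  minus <- minus[minus + 3 + 20 <= n]
  rbind(
    if (length(plus)) data.frame(strand = "+", pam_start = plus,
                                 start = plus - 20L, cut = plus - 3L),
    if (length(minus)) data.frame(strand = "-", pam_start = minus,
                                  start = minus + 3L, cut = minus + 6L))
}

# Vectorised translation oracle; internal-codon semantics (no initiator
# special-casing), matching how auxiliary mutations sit mid-CDS.
oracle_translate <- function(dna) {
  out <- as.character(Biostrings::translate(Biostrings::DNAStringSet(dna),
                                            no.init.codon = TRUE))
  if (length(dna) == 1L) out[[1]] else out
}

# Literal interval checks for indel/window intersection.
oracle_del_hits <- function(del_start, del_end, win) {
  del_start < win[2] && del_end > win[1]
}
oracle_ins_hits <- function(pos, win) {
  pos >= win[1] && pos <= win[2]
}

# Exhaustive blocking-mutation selection: enumerate every admissible
# subset of size <= 2 under the same admissibility rules as the
# implementation — candidate positions not altered by the edit,
# synonymous where coding (judged jointly: the second mutation's options
# are evaluated on the sequence with the first applied), deterministic
# preferred alternate per position, cumulative score within the
# threshold — and return the subset with the lexicographically greatest
# weight vector: strongest mutation first, ties broken by PAM proximity.
# Mirrors the selection objective, not the selection algorithm.
oracle_blocking_selection <- function(m, guide, edit, ref, ann = NULL) {
  intr <- ssodn:::intrinsic_disruption(m, guide, edit, ref)
  if (intr$score >= 0.985) return(character(0))
  labels <- c(paste0("S", 1:20), "P2", "P3")
  cand_at <- function(cur, exclude_coord = integer(0)) {
    cands <- list()
    for (lab in labels) {
      coord <- ssodn:::guide_coord(guide, lab)
      if (coord < 0 || coord >= nchar(ref)) next
      if (coord %in% intr$coords || coord %in% exclude_coord) next
      if (edit$start != edit$end && coord >= edit$start && coord < edit$end) next
      refb <- ssodn:::seq_base(ref, coord)
      alts <- setdiff(c("A", "C", "G", "T"), refb)
      if (!is.null(ann) && ssodn:::in_cds(ann, coord)) {
        alts <- alts[vapply(alts, function(a)
          isTRUE(as.logical(is_synonymous(cur, ann, coord, a))), logical(1))]
      }
      alt <- ssodn:::preferred_alt(lab, refb, alts)
      if (is.na(alt)) next
      w <- m$pssm[lab, alt]
      if (w > 0) cands[[length(cands) + 1L]] <-
        list(lab = lab, alt = alt, w = w, coord = coord,
             rank = ssodn:::pssm_position_rank(lab))
    }
    cands
  }
  better <- function(k1, k2) {
    if (is.null(k2)) return(TRUE)
    for (t in seq_along(k1)) {
      if (is.infinite(k1[t]) && is.infinite(k2[t])) next
      if (k1[t] != k2[t]) return(k1[t] > k2[t])
    }
    FALSE
  }
  base <- cand_at(ref)
  best <- character(0); best_key <- NULL
  for (c1 in base) {
    if (intr$score + c1$w > m$threshold) next
    k1 <- c(c1$w, -Inf, -c1$rank, -Inf)
    if (better(k1, best_key)) { best_key <- k1; best <- c1$lab }
    cur <- ref
    substr(cur, c1$coord + 1, c1$coord + 1) <- c1$alt
    for (c2 in cand_at(cur, exclude_coord = c1$coord)) {
      if (intr$score + c1$w + c2$w > m$threshold) next
      if (c2$w > c1$w ||
          (c2$w == c1$w && c2$rank < c1$rank)) next  # ordered pairs only
      k2 <- c(c1$w, c2$w, -c1$rank, -c2$rank)
      if (better(k2, best_key)) { best_key <- k2; best <- c(c1$lab, c2$lab) }
    }
  }
  best
}

# A random locus carrying one clean Cas9 site inside a scrubbed guard
# band, for design-level tests.
toy_cas9_locus <- function(seed, len = 300L, pam_at = len %/% 2L) {
  make_toy_locus(sim_spec(seed = seed, locus_length = len,
                          cas9_pam_plus = pam_at))
}
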