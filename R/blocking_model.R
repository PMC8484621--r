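# The PSSM of per-position relative HDR improvements, the linear
# blocking score, the 1.97 threshold logic, and greedy blocking-mutation
# selection.
#
# Positions are labelled S1..S20 (Cas9 spacer, 1 = PAM-distal 5' end,
# 20 = PAM-adjacent) and P1..P3 (PAM, P1 = the N of NGG).

pssm_position_labels <- function() c(paste0("S", 1:20), paste0("P", 1:3))

# Tie-break order for candidate positions: nearer the PAM first.
# P3 precedes P2 (the 'GG' to 'CC' exemplar mutates the terminal Gs).
pssm_position_rank <- function(label) {
  match(label, c("P3", "P2", "P1", paste0("S", 20:1)))
}

#' Default blocking-mutation PSSM
#'
#' Per-position, per-alternate-base weights of the relative HDR
#' improvement gained by a blocking mutation at that position. Weights
#' are base-uniform (no alternate base was universally preferred) and
#' decay PAM-distally: PAM positions 2 and 3 carry 0.985 each, calibrated
#' so that mutating both PAM G nucleotides scores exactly 1.97; P1 (the N
#' of NGG) carries 0 because mutating an unconstrained position cannot
#' block; spacer tiers are 0.80 (S17-S20), 0.55 (S13-S16), 0.35 (S9-S12)
#' and 0.10 (S1-S8). The spacer-tier magnitudes are package defaults that
#' reproduce the observed PAM-distal decay and can be overridden from a
#' TSV ([read_pssm()]) when an empirically fitted matrix is available.
#'
#' @return an `hdr_pssm` matrix (23 positions x 4 bases).
#' @export
#' @examples
#' default_pssm()["P2", ]
default_pssm <- function() {
  labels <- pssm_position_labels()
  w <- setNames(numeric(length(labels)), labels)
  w[paste0("S", 1:8)] <- 0.10
  w[paste0("S", 9:12)] <- 0.35
  w[paste0("S", 13:16)] <- 0.55
  w[paste0("S", 17:20)] <- 0.80
  w["P1"] <- 0
  w[c("P2", "P3")] <- 0.985
  m <- matrix(rep(w, times = 4L), nrow = length(labels),
              dimnames = list(labels, DNA_BASES))
  structure(m, class = c("hdr_pssm", "matrix"), enzyme = "Cas9")
}

#' Read / write a PSSM as TSV
#'
#' Three columns: `position` (S1..S20, P1..P3), `base`, `weight`.
#' Round-trips bit-exactly.
#'
#' @param pssm an `hdr_pssm` matrix.
#' @param path file path.
#' @return `read_pssm`: an `hdr_pssm`; `write_pssm`: `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  tab <- expand.grid(position = rownames(pssm), base = colnames(pssm),
                     stringsAsFactors = FALSE)
  tab$weight <- sprintf("%.17g", pssm[cbind(tab$position, tab$base)])
  tab <- tab[order(match(tab$position, pssm_position_labels()), tab$base), ]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
  labels <- pssm_position_labels()
  if (!all(tab$position %in% labels)) {
    ssodn_error("PSSM positions must be S1..S20 / P1..P3", "ssodn_bounds_error")
  }
  m <- matrix(0, nrow = length(labels), ncol = 4L,
              dimnames = list(labels, DNA_BASES))
  m[cbind(tab$position, tab$base)] <- tab$weight
  if (any(!is.finite(m)) || any(m < 0)) {
    ssodn_error("PSSM weights must be finite and >= 0", "ssodn_domain_error")
  }
  structure(m, class = c("hdr_pssm", "matrix"), enzyme = "Cas9")
}

#' Blocking model: PSSM, score threshold, and mutation budget
#'
#' The threshold (default 1.97) is the score of mutating both G
#' nucleotides of the Cas9 PAM under the default matrix: scores up to the
#' threshold predict improved HDR, scores above it have an uncertain,
#' possibly detrimental effect. At most `max_added` blocking mutations
#' are added (two; three or four gave no further benefit).
#'
#' @param pssm an `hdr_pssm` matrix.
#' @param threshold score threshold (> 0).
#' @param max_added maximum number of added blocking mutations.
#' @return a `blocking_model` object.
#' @export
blocking_model <- function(pssm = default_pssm(), threshold = 1.97,
                           max_added = 2L) {
  if (!is.numeric(threshold) || threshold <= 0) {
    ssodn_error("threshold must be > 0", "ssodn_domain_error")
  }
  structure(list(pssm = pssm, threshold = threshold,
                 max_added = as.integer(max_added)),
            class = "blocking_model")
}

#' Construct a mutation set
#'
#' A data.frame of single-base donor mutations: `pos_label` (spacer/PAM
#' label, may be `NA` for positions outside the protospacer),
#' `ref_coord` (0-based reference coordinate, may be `NA` when only the
#' label is known), `ref`, `alt`, and `class` (one of `edit_intrinsic`,
#' `blocking_PAM`, `blocking_seed`, `repair_track`).
#'
#' @param pos_label,ref_coord,ref,alt,class parallel vectors.
#' @return a `mutation_set` data.frame.
#' @export
mutation_set <- function(pos_label = character(), ref_coord = integer(),
                         ref = character(), alt = character(),
                         class = character()) {
  n <- max(length(pos_label), length(ref_coord), length(alt))
  if (n == 0L) {
    out <- data.frame(pos_label = character(), ref_coord = integer(),
                      ref = character(), alt = character(),
                      class = character(), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(pos_label = rep_len(as.character(pos_label), n),
                      ref_coord = rep_len(as.integer(ref_coord), n),
                      ref = rep_len(as.character(ref), n),
                      alt = rep_len(as.character(alt), n),
                      class = rep_len(as.character(class), n),
                      stringsAsFactors = FALSE)
    key <- ifelse(is.na(out$ref_coord), out$pos_label, out$ref_coord)
    if (anyDuplicated(key)) {
      ssodn_error("mutation positions must be unique within a set", "ssodn_bounds_error")
    }
  }
  class(out) <- c("mutation_set", "data.frame")
  out
}

#' Parse a mutation-set string
#'
#' Accepts the compact form used by the command line, e.g.
#' `"P2:G>C,P3:G>C"` or `"S14:A>T"`.
#'
#' @param spec character scalar.
#' @return a [mutation_set()].
#' @export
parse_mutation_spec <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  if (length(parts) == 0L) return(mutation_set())
  m <- regmatches(parts, regexec("^([SP][0-9]+):([ACGT])>([ACGT])$", parts))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    ssodn_error(sprintf("cannot parse mutation '%s' (expected e.g. P2:G>C)",
                        parts[bad][1]), "ssodn_usage_error")
  }
  mutation_set(pos_label = vapply(m, `[`, character(1), 2L),
               ref_coord = NA_integer_,
               ref = vapply(m, `[`, character(1), 3L),
               alt = vapply(m, `[`, character(1), 4L),
               class = "blocking_PAM")
}

mutation_labels <- function(mutations, guide = NULL) {
  labs <- mutations$pos_label
  need <- is.na(labs) & !is.na(mutations$ref_coord)
  if (any(need)) {
    if (is.null(guide)) return(labs)
    labs[need] <- map_guide_position(guide, mutations$ref_coord[need])
  }
  labs
}

#' Blocking score of a mutation set
#'
#' Sum of PSSM weights at the mutated spacer/PAM positions (a linear
#' combination; additive over disjoint sets). Mutations whose position
#' falls outside the protospacer and PAM do not block re-cleavage and are
#' excluded with a warning. A "mutation" whose alternate equals the
#' reference base contributes 0.
#'
#' @param model a [blocking_model()].
#' @param mutations a [mutation_set()].
#' @param guide optional guide row, used to map reference coordinates to
#'   spacer/PAM labels when `pos_label` is missing.
#' @return numeric score.
#' @export
#' @examples
#' blocking_score(blocking_model(), parse_mutation_spec("P2:G>C,P3:G>C"))
blocking_score <- function(model, mutations, guide = NULL) {
  if (nrow(mutations) == 0L) return(0)
  labs <- mutation_labels(mutations, guide)
  outside <- is.na(labs)
  if (any(outside)) {
    ssodn_warning(sprintf(
      "%d mutation(s) outside the protospacer/PAM excluded from the blocking score",
      sum(outside)), "ssodn_outside_protospacer_warning")
  }
  keep <- !outside &
    (is.na(mutations$ref) | is.na(mutations$alt) | mutations$ref != mutations$alt)
  if (!any(keep)) return(0)
  alts <- mutations$alt[keep]
  alts[is.na(alts)] <- "A"  # base-uniform matrix: any column
  sum(model$pssm[cbind(labs[keep], alts)])
}

#' Predicted effect of a blocking score
#'
#' `none` for a zero score, `beneficial` for scores up to the threshold
#' (the boundary itself is the best observed design, two PAM-G
#' mutations), `uncertain` above it.
#'
#' @param model a [blocking_model()].
#' @param score numeric score, >= 0.
#' @return `"none"`, `"beneficial"` or `"uncertain"`.
#' @export
predict_effect <- function(model, score) {
  if (!is.numeric(score) || is.na(score) || score < 0) {
    ssodn_error("blocking score must be >= 0", "ssodn_domain_error")
  }
  if (score == 0) "none"
  else if (score <= model$threshold) "beneficial"
  else "uncertain"
}

# Spacer/PAM labels disrupted by the edit itself. Substitutions disrupt
# the positions whose base they change; an indel inside the
# protospacer/PAM shifts the register of everything between the edit and
# the PAM, so all those positions count as disrupted.
intrinsic_disruption <- function(model, guide, edit, ref) {
  g <- as_guide_row(guide)
  lo <- min(g$start, g$pam_start); hi <- max(g$end, g$pam_end)
  is_sub <- (edit$end - edit$start) == nchar(edit$replacement) &&
    edit$end > edit$start
  coords <- integer(0)
  if (is_sub) {
    pos <- seq.int(edit$start, edit$end - 1L)
    changed <- vapply(seq_along(pos), function(i) {
      seq_base(ref, pos[i]) != substr(edit$replacement, i, i)
    }, logical(1))
    coords <- pos[changed]
  } else if (edit_hits_protospacer(g, edit)) {
    # indel: register shifts from the edit toward the PAM
    pam_right <- g$pam_start >= g$start  # PAM on the right in plus coords?
    coords <- if (pam_right) seq.int(max(lo, edit$start), hi - 1L)
              else seq.int(lo, min(hi, edit$end) - 1L)
  }
  coords <- coords[coords >= lo & coords < hi]
  labs <- map_guide_position(g, coords)
  labs <- labs[!is.na(labs)]
  score <- if (length(labs)) sum(model$pssm[labs, 1L]) else 0
  list(score = score, labels = labs, coords = coords)
}

# Preferred alternate base at a spacer/PAM position.
# PAM G positions in non-coding context take the G->C transversion (the
# 'GG' to 'CC' exemplar); otherwise the first admissible base in
# A < C < G < T order.
preferred_alt <- function(label, refb, admissible) {
  if (length(admissible) == 0L) return(NA_character_)
  if (label %in% c("P2", "P3") && refb == "G" && "C" %in% admissible) return("C")
  sort(admissible)[1L]
}

blocking_class <- function(label) {
  if (grepl("^P", label)) "blocking_PAM" else "blocking_seed"
}

#' Select blocking mutations for a Cas9 donor design
#'
#' Three-step rule. (1) Compute the edit's intrinsic disruption score:
#' the PSSM score of the protospacer/PAM positions the edit itself
#' alters. (2) If the intrinsic score is at least 0.985 (one PAM-G
#' equivalent) the edit already blocks re-cleavage and no mutation is
#' added. (3) Otherwise candidate mutations are added greedily in
#' descending PSSM weight (ties: position nearer the PAM first, then
#' alternate base A < C < G < T), restricted to synonymous options
#' wherever the coding annotation covers the position, skipping any
#' candidate that would push the cumulative (intrinsic + added) score
#' above the threshold, until `max_added` mutations are selected.
#'
#' @param model a [blocking_model()].
#' @param guide one row of a [find_guides()] table (Cas9).
#' @param edit an [edit_spec()].
#' @param ref reference sequence.
#' @param annotation optional [coding_annotation()].
#' @param max_added override of the model's mutation budget.
#' @return a `blocking_selection` list: `mutations` ([mutation_set()]),
#'   `score` (cumulative = intrinsic + added), `intrinsic`, `note`.
#' @export
select_blocking_mutations <- function(model, guide, edit, ref,
                                      annotation = NULL, max_added = NULL) {
  g <- as_guide_row(guide)
  ref <- dna(ref)
  check_edit_bounds(edit, ref)
  max_added <- max_added %||% model$max_added
  intr <- intrinsic_disruption(model, g, edit, ref)
  res <- function(muts, score, note = NULL) {
    structure(list(mutations = muts, score = score,
                   intrinsic = intr$score, note = note),
              class = "blocking_selection")
  }
  if (intr$score >= 0.985) {
    return(res(mutation_set(), intr$score,
               "edit disrupts the protospacer/PAM; no blocking mutation needed"))
  }
  labels <- pssm_position_labels()
  weights <- model$pssm[labels, 1L]
  cand <- data.frame(label = labels, weight = weights,
                     rank = pssm_position_rank(labels),
                     stringsAsFactors = FALSE)
  cand <- cand[cand$weight > 0, , drop = FALSE]
  cand <- cand[order(-cand$weight, cand$rank), , drop = FALSE]

  chosen <- list()
  cum <- intr$score
  none_admissible <- TRUE
  cur <- ref  # synonymy is judged jointly: prior picks are applied first
  for (i in seq_len(nrow(cand))) {
    if (length(chosen) >= max_added) break
    label <- cand$label[i]
    coord <- guide_coord(g, label)
    if (coord < 0L || coord >= nchar(ref)) next
    if (coord %in% intr$coords) next
    in_edit <- if (edit$start == edit$end) FALSE
               else coord >= edit$start && coord < edit$end
    if (in_edit) next
    refb <- seq_base(ref, coord)
    if (!refb %in% DNA_BASES) next
    alts <- setdiff(DNA_BASES, refb)
    if (!is.null(annotation) && in_cds(annotation, coord)) {
      syn <- vapply(alts, function(a)
        isTRUE(as.logical(is_synonymous(cur, annotation, coord, a))),
        logical(1))
      alts <- alts[syn]
    }
    alt <- preferred_alt(label, refb, alts)
    if (is.na(alt)) next
    none_admissible <- FALSE
    w <- cand$weight[i]
    if (cum + w > model$threshold) next
    chosen[[length(chosen) + 1L]] <- data.frame(
      pos_label = label, ref_coord = coord, ref = refb, alt = alt,
      class = blocking_class(label), stringsAsFactors = FALSE)
    substr(cur, coord + 1L, coord + 1L) <- alt
    cum <- cum + w
  }
  if (length(chosen) == 0L) {
    note <- if (none_admissible) {
      "no admissible blocking mutation (coding constraints leave no synonymous option in the protospacer/PAM)"
    } else {
      "no blocking mutation fits under the score threshold"
    }
    return(res(mutation_set(), cum, note))
  }
  muts <- do.call(rbind, chosen)
  class(muts) <- c("mutation_set", "data.frame")
  res(muts, cum)
}

#' @export
print.blocking_selection <- function(x, ...) {
  cat(sprintf("<blocking_selection> %d mutation(s), score %.3f (intrinsic %.3f)\n",
              nrow(x$mutations), x$score, x$intrinsic))
  if (nrow(x$mutations)) {
    cat(paste0("  ", x$mutations$pos_label, ": ", x$mutations$ref, ">",
               x$mutations$alt, " [", x$mutations$class, "]",
               collapse = "\n"), "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
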