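# End-to-end donor construction: strand choice, repair-track mutations,
# homology arms, length validation, and enzyme-specific design flows
# (Cas9, D10A pairs, Cas12a).

#' Donor design configuration
#'
#' @param arm_length default homology-arm length in nt, measured beyond
#'   both the cut site and the farthest edit/mutation boundary on each
#'   side (40 nt; symmetric arms; asymmetric lengths can be passed to
#'   [build_donor()] directly).
#' @param min_arm hard floor on arm length (30 nt; shorter arms require
#'   `allow_short_arms`). Oligo synthesis supports arms down to 20 nt.
#' @param max_guide_distance maximum edit-to-cut distance for plain Cas9
#'   (and Cas12a) guide selection (15 nt).
#' @param track_spacing spacing of repair-track mutations (5 nt, within
#'   the observed 3-7 nt range).
#' @param track_trigger edit-to-cut distance above which repair-track
#'   mutations are added and the distance-dependent strand rule applies
#'   (10 nt).
#' @param strand_at_cut donor strand for Cas9 edits at or near the cut
#'   (`"NT"`; the preference at the cut is cell-type dependent).
#' @param spacing_min,spacing_max paired-nickase nick spacing bounds
#'   (40/68 nt, inclusive).
#' @param cas12a_window favoured Cas12a spacer-position window
#'   (`c(12, 16)`).
#' @param max_length ssODN synthesis cap (200 nt).
#' @param allow_long permit donors beyond `max_length`.
#' @param allow_short_arms permit arms below `min_arm`.
#' @param end_modification metadata flag recorded on designs
#'   (`"none"`, `"PS"` or `"AltR"`); oligo chemistry is not modelled.
#' @return a `design_config` list.
#' @export
design_config <- function(arm_length = 40L, min_arm = 30L,
                          max_guide_distance = 15L, track_spacing = 5L,
                          track_trigger = 10L, strand_at_cut = "NT",
                          spacing_min = 40L, spacing_max = 68L,
                          cas12a_window = c(12L, 16L), max_length = 200L,
                          allow_long = FALSE, allow_short_arms = FALSE,
                          end_modification = c("none", "PS", "AltR")) {
  end_modification <- match.arg(end_modification)
  cfg <- list(arm_length = as.integer(arm_length),
              min_arm = as.integer(min_arm),
              max_guide_distance = as.integer(max_guide_distance),
              track_spacing = as.integer(track_spacing),
              track_trigger = as.integer(track_trigger),
              strand_at_cut = strand_at_cut,
              spacing_min = as.integer(spacing_min),
              spacing_max = as.integer(spacing_max),
              cas12a_window = as.integer(cas12a_window),
              max_length = as.integer(max_length),
              allow_long = isTRUE(allow_long),
              allow_short_arms = isTRUE(allow_short_arms),
              end_modification = end_modification)
  if (any(vapply(cfg[c("arm_length", "max_guide_distance", "track_spacing",
                       "track_trigger", "spacing_min", "spacing_max",
                       "max_length")], function(v) v <= 0L, logical(1)))) {
    ssodn_error("configuration lengths must be positive", "ssodn_domain_error")
  }
  if (!strand_at_cut %in% c("NT", "T")) {
    ssodn_error("strand_at_cut must be 'NT' or 'T'", "ssodn_usage_error")
  }
  structure(cfg, class = "design_config")
}

#' Read a design configuration from YAML or JSON
#'
#' Keys mirror [design_config()] arguments; unknown keys are rejected.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `design_config`.
#' @export
read_design_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) read_yaml(path)
          else read_json(path, simplifyVector = TRUE)
  known <- names(formals(design_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    ssodn_error(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
                "ssodn_usage_error")
  }
  do.call(design_config, vals)
}

#' Choose the donor strand
#'
#' Cas9: T strand for PAM-proximal edits, NT strand for PAM-distal
#' edits, both rules applying when the edit is beyond the repair-track
#' trigger distance; at or near the cut the configured default (NT) is
#' used, with a note that the preference there is cell-type dependent.
#' Paired D10A nickases show no strand preference, so both strands
#' (`"both"` = top and bottom) are emitted. Cas12a always takes the NT
#' strand (the T strand consistently reduces total editing).
#'
#' @param enzyme an [enzyme_profile()].
#' @param placement an [classify_placement()] result.
#' @param config a [design_config()].
#' @return list with `strand` (`"T"`, `"NT"` or `"both"`) and `rationale`.
#' @export
choose_strand <- function(enzyme, placement, config = design_config()) {
  if (isTRUE(enzyme$nickase_pair)) {
    return(list(strand = "both",
                rationale = "paired D10A nicks show no donor strand preference; top and bottom strands emitted"))
  }
  if (enzyme$name == "Cas12a") {
    return(list(strand = "NT",
                rationale = "Cas12a: the T strand universally reduces total editing; NT strand used"))
  }
  if (placement$side == "at_cut" || placement$distance <= config$track_trigger) {
    return(list(strand = config$strand_at_cut,
                rationale = sprintf(
                  "edit at/near the cut (%d nt): strand preference is cell-type dependent; default %s strand used",
                  placement$distance, config$strand_at_cut)))
  }
  if (placement$side == "PAM_proximal") {
    list(strand = "T",
         rationale = "PAM-proximal edit: T strand consistently favoured")
  } else {
    list(strand = "NT",
         rationale = "PAM-distal edit: NT strand consistently delivers the highest HDR")
  }
}

# A<->C and G<->T transversions (purine<->pyrimidine swaps that keep the
# choice deterministic).
transversion_partner <- function(b) chartr("ACGT", "CATG", b)

#' Repair-track mutations between the cut site and a distant edit
#'
#' For edits farther than the trigger distance from the cut, candidate
#' positions are placed every `track_spacing` nt along the repair track
#' (the donor segment between the cut and the edit), exclusive of both
#' endpoints. Where the coding annotation covers a candidate, the
#' position slides up to 2 nt to the nearest synonymous-capable spot
#' (skipped when none exists); otherwise a transversion (A<->C, G<->T)
#' is used.
#'
#' @param ref reference sequence.
#' @param guide one row of a [find_guides()] table.
#' @param edit an [edit_spec()].
#' @param annotation optional [coding_annotation()].
#' @param config a [design_config()].
#' @param applied a [mutation_set()] of mutations already placed on the
#'   donor (e.g. a PAM blocking mutation); synonymy of track mutations is
#'   judged jointly with them, and their positions are not reused.
#' @return a [mutation_set()] (possibly empty), class `repair_track`.
#' @export
repair_track_mutations <- function(ref, guide, edit, annotation = NULL,
                                   config = design_config(),
                                   applied = mutation_set()) {
  ref <- dna(ref)
  g <- as_guide_row(guide)
  placement <- classify_placement(g, edit)
  if (placement$distance <= config$track_trigger) return(mutation_set())
  cuts <- cut_positions(g)
  cut <- cuts[which.min(vapply(cuts, boundary_distance, integer(1), edit = edit))]
  b <- if (abs(cut - edit$start) <= abs(cut - edit$end)) edit$start else edit$end
  dir <- if (b >= cut) 1L else -1L
  rows <- list()
  used <- applied$ref_coord[!is.na(applied$ref_coord)]
  cur <- ref
  for (j in seq_len(nrow(applied))) {
    substr(cur, applied$ref_coord[j] + 1L, applied$ref_coord[j] + 1L) <-
      applied$alt[j]
  }
  k <- 1L
  repeat {
    coord <- if (dir > 0L) cut + k * config$track_spacing
             else cut - 1L - k * config$track_spacing
    inside <- if (dir > 0L) coord < b else coord >= b
    if (!inside) break
    k <- k + 1L
    if (coord < 0L || coord >= nchar(ref)) next
    in_edit <- if (edit$start == edit$end) FALSE
               else coord >= edit$start && coord < edit$end
    if (in_edit) next
    pick <- NULL
    if (!is.null(annotation) && in_cds(annotation, coord)) {
      for (off in c(0L, 1L, -1L, 2L, -2L)) {
        p <- coord + off
        if (p < 0L || p >= nchar(ref) || p %in% used) next
        in_edit_p <- if (edit$start == edit$end) FALSE
                     else p >= edit$start && p < edit$end
        if (in_edit_p) next
        refb <- seq_base(ref, p)
        alts <- setdiff(DNA_BASES, refb)
        syn <- alts[vapply(alts, function(a)
          isTRUE(as.logical(is_synonymous(cur, annotation, p, a))), logical(1))]
        if (length(syn)) {
          tv <- transversion_partner(refb)
          alt <- if (tv %in% syn) tv else sort(syn)[1L]
          pick <- list(coord = p, ref = refb, alt = alt)
          break
        }
      }
    } else {
      if (coord %in% used) next
      refb <- seq_base(ref, coord)
      pick <- list(coord = coord, ref = refb, alt = transversion_partner(refb))
    }
    if (is.null(pick)) next
    used <- c(used, pick$coord)
    substr(cur, pick$coord + 1L, pick$coord + 1L) <- pick$alt
    rows[[length(rows) + 1L]] <- data.frame(
      pos_label = map_guide_position(g, pick$coord),
      ref_coord = pick$coord, ref = pick$ref, alt = pick$alt,
      class = "repair_track", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(mutation_set())
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_coord), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutation_set", "data.frame")
  out
}

dedupe_mutations <- function(mutations) {
  if (nrow(mutations) == 0L) return(mutations)
  keep <- !duplicated(mutations$ref_coord)
  out <- mutations[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mutation_set", "data.frame")
  out
}

#' Build an ssODN donor
#'
#' Assembles `[5' arm][edited + mutated core][3' arm]` on the plus strand
#' and reverse-complements it when the T (or bottom) strand is requested.
#' Arms extend at least `arm_5`/`arm_3` nt beyond both the cut site(s)
#' and the farthest edit/mutation boundary on each side. The total length
#' is validated against the 200-nt synthesis cap and arms against the
#' 30-nt floor (both overridable via the configuration).
#'
#' @param ref reference sequence.
#' @param guide one row of a [find_guides()] table, or `NULL` when `pair`
#'   is given.
#' @param pair one row of a [find_nickase_pairs()] table, or `NULL`.
#' @param edit an [edit_spec()].
#' @param mutations a [mutation_set()] of auxiliary mutations.
#' @param strand `"NT"`, `"T"`, `"top"` or `"bottom"`. NT/top donors carry
#'   the plus-strand (protospacer + PAM) sense; T/bottom donors are their
#'   reverse complements.
#' @param config a [design_config()].
#' @param arm_5,arm_3 arm lengths (default `config$arm_length`).
#' @param model [blocking_model()] used to record the design's blocking
#'   score.
#' @param rationale free-text rationale recorded on the design.
#' @return a `donor_design` object.
#' @export
build_donor <- function(ref, guide = NULL, pair = NULL, edit,
                        mutations = mutation_set(), strand = "NT",
                        config = design_config(), arm_5 = NULL, arm_3 = NULL,
                        model = blocking_model(), rationale = NULL) {
  ref <- dna(ref)
  check_edit_bounds(edit, ref)
  if (!strand %in% c("NT", "T", "top", "bottom")) {
    ssodn_error("strand must be NT, T, top or bottom", "ssodn_usage_error")
  }
  arm_5 <- as.integer(arm_5 %||% config$arm_length)
  arm_3 <- as.integer(arm_3 %||% config$arm_length)
  if (min(arm_5, arm_3) < 1L) ssodn_error("arms must be >= 1 nt", "ssodn_arm_error")
  warnings <- character(0)
  if (min(arm_5, arm_3) < config$min_arm) {
    if (!config$allow_short_arms) {
      ssodn_error(sprintf("homology arm below the %d-nt floor (got %d); set allow_short_arms to override",
                          config$min_arm, min(arm_5, arm_3)),
                  "ssodn_arm_error")
    }
    warnings <- c(warnings, sprintf("arm below the %d-nt floor", config$min_arm))
  }
  cuts <- if (!is.null(pair)) {
    p <- as_pair_row(pair)
    c(p$nick_left, p$nick_right)
  } else if (!is.null(guide)) {
    unname(cut_positions(guide))
  } else {
    ssodn_error("either guide or pair must be supplied", "ssodn_usage_error")
  }
  mut_coords <- mutations$ref_coord[!is.na(mutations$ref_coord)]
  if (length(mut_coords) != nrow(mutations)) {
    ssodn_error("all donor mutations need reference coordinates", "ssodn_bounds_error")
  }
  core_lo <- min(c(cuts, edit$start, mut_coords))
  core_hi <- max(c(cuts, edit$end, if (length(mut_coords)) mut_coords + 1L))
  donor_start <- core_lo - arm_5
  donor_end <- core_hi + arm_3
  if (donor_start < 0L || donor_end > nchar(ref)) {
    ssodn_error("reference too short for the requested homology arms", "ssodn_bounds_error")
  }
  delta <- edit_length_delta(edit)
  total <- (donor_end - donor_start) + delta
  if (total > config$max_length && !config$allow_long) {
    ssodn_error(sprintf(
      "donor length %d exceeds the %d-nt synthesis cap by %d nt (set allow_long to override)",
      total, config$max_length, total - config$max_length),
      "ssodn_length_error")
  }
  # verify recorded reference bases, then apply edit + mutations
  if (nrow(mutations)) {
    obs <- vapply(mutations$ref_coord, function(i) seq_base(ref, i), character(1))
    stated <- mutations$ref
    bad <- !is.na(stated) & stated != obs
    if (any(bad)) {
      ssodn_error("mutation reference base does not match the reference sequence",
                  "ssodn_bounds_error")
    }
    in_edit <- mutations$ref_coord >= edit$start & mutations$ref_coord < edit$end
    if (any(in_edit)) {
      ssodn_error("auxiliary mutations may not fall inside the edit interval",
                  "ssodn_bounds_error")
    }
  }
  seq_plus <- seq_sub(ref, donor_start, donor_end)
  # apply point mutations (coordinates relative to donor_start)
  for (i in seq_len(nrow(mutations))) {
    rel <- mutations$ref_coord[i] - donor_start
    substr(seq_plus, rel + 1L, rel + 1L) <- mutations$alt[i]
  }
  seq_plus <- seq_splice(seq_plus, edit$start - donor_start,
                         edit$end - donor_start, edit$replacement)
  stopifnot(nchar(seq_plus) == total)
  sequence <- if (strand %in% c("T", "bottom")) revcomp(seq_plus) else seq_plus
  score <- if (!is.null(guide)) {
    withCallingHandlers(
      blocking_score(model, mutations, guide),
      ssodn_outside_protospacer_warning = function(w) invokeRestart("muffleWarning"))
  } else 0
  structure(list(
    id = sprintf("%s_%s_%s",
                 if (!is.null(pair)) as_pair_row(pair)$pair_id
                 else as_guide_row(guide)$id,
                 edit$label, strand),
    enzyme = if (!is.null(pair)) "Cas9-D10A-pair" else as_guide_row(guide)$enzyme,
    guide_id = if (!is.null(pair)) NA_character_ else as_guide_row(guide)$id,
    pair_id = if (!is.null(pair)) as_pair_row(pair)$pair_id else NA_character_,
    strand = strand,
    sequence = sequence,
    length = total,
    arm_5 = arm_5, arm_3 = arm_3,
    donor_ref_start = donor_start, donor_ref_end = donor_end,
    edit = edit,
    mutations = mutations,
    blocking_score = score,
    end_modification = config$end_modification,
    rationale = rationale,
    warnings = warnings
  ), class = "donor_design")
}

#' @export
print.donor_design <- function(x, ...) {
  cat(sprintf("<donor_design> %s\n  enzyme %s, strand %s, %d nt (arms %d/%d), blocking score %.3f\n",
              x$id, x$enzyme, x$strand, x$length, x$arm_5, x$arm_3,
              x$blocking_score))
  if (nrow(x$mutations)) {
    cat("  mutations:",
        paste0(x$mutations$ref_coord, ":", x$mutations$ref, ">",
               x$mutations$alt, "(", x$mutations$class, ")",
               collapse = " "), "\n")
  }
  if (!is.null(x$rationale)) cat("  rationale:", x$rationale, "\n")
  cat("  ", x$sequence, "\n", sep = "")
  invisible(x)
}

# A single PAM blocking mutation (P3 preferred, then P2), synonymous when
# the annotation covers the position.
single_pam_mutation <- function(model, guide, edit, ref, annotation = NULL) {
  g <- as_guide_row(guide)
  for (label in c("P3", "P2")) {
    coord <- guide_coord(g, label)
    if (coord < 0L || coord >= nchar(ref)) next
    in_edit <- if (edit$start == edit$end) FALSE
               else coord >= edit$start && coord < edit$end
    if (in_edit) next
    refb <- seq_base(ref, coord)
    if (!refb %in% DNA_BASES) next
    alts <- setdiff(DNA_BASES, refb)
    if (!is.null(annotation) && in_cds(annotation, coord)) {
      alts <- alts[vapply(alts, function(a)
        isTRUE(as.logical(is_synonymous(ref, annotation, coord, a))), logical(1))]
    }
    alt <- preferred_alt(label, refb, alts)
    if (is.na(alt)) next
    return(mutation_set(pos_label = label, ref_coord = coord, ref = refb,
                        alt = alt, class = "blocking_PAM"))
  }
  mutation_set()
}

#' Design Cas9 ssODN donors for an edit
#'
#' Full pipeline: guide discovery, ranking (activity over proximity),
#' placement classification, strand choice, blocking/repair-track
#' mutation selection, and donor assembly. Edits at or near the cut get
#' up to two PSSM-selected blocking mutations; PAM-proximal edits beyond
#' the repair-track trigger get a single PAM mutation plus repair-track
#' mutations on the T strand; PAM-distal edits get repair-track mutations
#' only, on the NT strand (a PAM mutation adds nothing there).
#'
#' @param ref reference sequence.
#' @param edit an [edit_spec()].
#' @param annotation optional [coding_annotation()]; when supplied, every
#'   auxiliary mutation is silent.
#' @param config a [design_config()].
#' @param activity optional per-guide activity scores (see
#'   [rank_guides()]).
#' @param model a [blocking_model()].
#' @return list of `donor_design` objects (best first); attribute
#'   `diagnostic` explains an empty result.
#' @export
design_cas9 <- function(ref, edit, annotation = NULL,
                        config = design_config(), activity = NULL,
                        model = blocking_model()) {
  ref <- dna(ref)
  check_edit_bounds(edit, ref)
  enzyme <- enzyme_profile("Cas9")
  guides <- find_guides(ref, enzyme)
  ranked <- rank_guides(guides, edit, config$max_guide_distance, activity)
  if (nrow(ranked) == 0L) {
    out <- list()
    attr(out, "diagnostic") <- attr(ranked, "diagnostic") %||%
      "no usable Cas9 guide; consider design_nickase() or design_cas12a()"
    return(out)
  }
  designs <- list()
  for (i in seq_len(nrow(ranked))) {
    g <- ranked[i, ]
    placement <- classify_placement(g, edit)
    strand <- choose_strand(enzyme, placement, config)
    if (placement$distance <= config$track_trigger) {
      sel <- select_blocking_mutations(model, g, edit, ref, annotation)
      muts <- sel$mutations
      why <- c(strand$rationale, sel$note)
    } else if (placement$side == "PAM_proximal") {
      pam_mut <- single_pam_mutation(model, g, edit, ref, annotation)
      muts <- dedupe_mutations(rbind(
        pam_mut,
        repair_track_mutations(ref, g, edit, annotation, config,
                               applied = pam_mut)))
      why <- c(strand$rationale,
               "PAM-proximal beyond the track trigger: single PAM mutation + repair-track mutations")
    } else {
      muts <- repair_track_mutations(ref, g, edit, annotation, config)
      why <- c(strand$rationale,
               "PAM-distal beyond the track trigger: repair-track mutations only (PAM mutation adds no benefit)")
    }
    d <- tryCatch(
      build_donor(ref, guide = g, edit = edit, mutations = muts,
                  strand = strand$strand, config = config, model = model,
                  rationale = paste(why, collapse = "; ")),
      ssodn_error = function(e) NULL)
    if (!is.null(d)) designs[[length(designs) + 1L]] <- d
  }
  if (length(designs) == 0L) {
    attr(designs, "diagnostic") <- "all candidate donors failed validation (length/arm constraints)"
  }
  designs
}

#' Design paired-nickase (Cas9 D10A) donors for an edit
#'
#' Enumerates PAM-out guide pairs with 40-68 nt nick spacing that bracket
#' the edit and emits both top- and bottom-strand donors for each pair,
#' with arms measured beyond both nick sites and the edit. No blocking
#' mutations are added: re-cleavage of the repaired duplex would require
#' both nicks to be restored.
#'
#' @param ref reference sequence.
#' @param edit an [edit_spec()].
#' @param annotation unused; accepted for interface symmetry.
#' @param config a [design_config()].
#' @return list of `donor_design` objects; attribute `diagnostic`
#'   explains an empty result.
#' @export
design_nickase <- function(ref, edit, annotation = NULL,
                           config = design_config()) {
  ref <- dna(ref)
  check_edit_bounds(edit, ref)
  pairs <- find_nickase_pairs(ref, edit, config$spacing_min,
                              config$spacing_max)
  if (nrow(pairs) == 0L) {
    out <- list()
    attr(out, "diagnostic") <- attr(pairs, "diagnostic")
    return(out)
  }
  designs <- list()
  for (i in seq_len(nrow(pairs))) {
    for (strand in c("top", "bottom")) {
      d <- tryCatch(
        build_donor(ref, pair = pairs[i, ], edit = edit,
                    mutations = mutation_set(), strand = strand,
                    config = config,
                    rationale = "D10A pair: edit between the nicks; no strand preference; no blocking mutations needed"),
        ssodn_error = function(e) NULL)
      if (!is.null(d)) designs[[length(designs) + 1L]] <- d
    }
  }
  if (length(designs) == 0L) {
    attr(designs, "diagnostic") <- "all candidate pair donors failed validation (length/arm constraints)"
  }
  designs
}

# One blocking mutation for a Cas12a design whose edit lies outside the
# protospacer: a synonymous protospacer option near spacer position 14
# when the annotation allows it, else the PAM TTTV -> TVTV mutation
# (second PAM position, T -> G transversion).
cas12a_blocking_mutation <- function(guide, edit, ref, annotation = NULL) {
  g <- as_guide_row(guide)
  if (!is.null(annotation)) {
    order14 <- order(abs(1:21 - 14L), 1:21)
    for (k in order14) {
      coord <- guide_coord(g, paste0("S", k))
      if (coord < 0L || coord >= nchar(ref)) next
      if (!in_cds(annotation, coord)) next
      refb <- seq_base(ref, coord)
      alts <- setdiff(DNA_BASES, refb)
      syn <- alts[vapply(alts, function(a)
        isTRUE(as.logical(is_synonymous(ref, annotation, coord, a))), logical(1))]
      if (length(syn)) {
        tv <- transversion_partner(refb)
        alt <- if (tv %in% syn) tv else sort(syn)[1L]
        return(mutation_set(pos_label = paste0("S", k), ref_coord = coord,
                            ref = refb, alt = alt, class = "blocking_seed"))
      }
    }
  }
  coord <- guide_coord(g, "P2")
  refb <- seq_base(ref, coord)
  mutation_set(pos_label = "P2", ref_coord = coord, ref = refb,
               alt = transversion_partner(refb), class = "blocking_PAM")
}

#' Design Cas12a ssODN donors for an edit
#'
#' Guides placing the edit at spacer positions 12-16 are ranked first and
#' carry no blocking mutations (the insertion itself disrupts subsequent
#' cleavage). Guides whose protospacer/PAM the edit does not touch get
#' exactly one blocking mutation: a synonymous protospacer option near
#' position 14 when a coding annotation is given, otherwise the PAM
#' TTTV -> TVTV mutation. The donor strand is always NT.
#'
#' @param ref reference sequence.
#' @param edit an [edit_spec()].
#' @param annotation optional [coding_annotation()].
#' @param config a [design_config()].
#' @return list of `donor_design` objects; attribute `diagnostic`
#'   explains an empty result.
#' @export
design_cas12a <- function(ref, edit, annotation = NULL,
                          config = design_config()) {
  ref <- dna(ref)
  check_edit_bounds(edit, ref)
  enzyme <- enzyme_profile("Cas12a")
  guides <- find_guides(ref, enzyme)
  if (nrow(guides) == 0L) {
    out <- list()
    attr(out, "diagnostic") <- "no TTTV PAM on either strand; Cas12a cannot target this locus"
    return(out)
  }
  placements <- lapply(seq_len(nrow(guides)), function(i)
    classify_placement(guides[i, ], edit, window = config$cas12a_window))
  dist <- vapply(placements, function(p) p$distance, integer(1))
  in_win <- vapply(placements, function(p) isTRUE(p$in_spacer_window), logical(1))
  keep <- dist <= config$max_guide_distance
  if (!any(keep)) {
    out <- list()
    attr(out, "diagnostic") <- sprintf(
      "no Cas12a cut within %d nt of the edit", config$max_guide_distance)
    return(out)
  }
  idx <- which(keep)
  ord <- idx[order(!in_win[idx], dist[idx])]
  designs <- list()
  for (i in ord) {
    g <- guides[i, ]
    if (in_win[i] || edit_hits_protospacer(g, edit)) {
      muts <- mutation_set()
      why <- if (in_win[i]) {
        "edit within spacer positions 12-16: optimal Cas12a placement; insertion disrupts re-cleavage, no blocking mutation"
      } else {
        "edit disrupts the protospacer; no blocking mutation"
      }
    } else {
      muts <- cas12a_blocking_mutation(g, edit, ref, annotation)
      why <- "edit outside the protospacer: one blocking mutation restores HDR (PAM TVTV or protospacer near position 14)"
    }
    d <- tryCatch(
      build_donor(ref, guide = g, edit = edit, mutations = muts,
                  strand = "NT", config = config,
                  rationale = paste("NT strand (Cas12a universal preference);", why)),
      ssodn_error = function(e) NULL)
    if (!is.null(d)) designs[[length(designs) + 1L]] <- d
  }
  if (length(designs) == 0L) {
    attr(designs, "diagnostic") <- "all candidate donors failed validation (length/arm constraints)"
  }
  designs
}

#' Write donor designs as FASTA and companion TSV
#'
#' @param designs list of `donor_design` objects.
#' @param prefix output path prefix; writes `<prefix>.fasta` and
#'   `<prefix>.tsv`.
#' @return the two paths, invisibly.
#' @export
write_designs <- function(designs, prefix) {
  fa <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  if (length(designs) == 0L) {
    writeLines(character(0), fa)
    tab <- data.frame(id = character(), enzyme = character(),
                      guide = character(), strand = character(),
                      length = integer(), arm_5 = integer(),
                      arm_3 = integer(), mutations = character(),
                      blocking_score = numeric(), warnings = character())
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(c(fasta = fa, tsv = tsv)))
  }
  seqs <- vapply(designs, function(d) d$sequence, character(1))
  names(seqs) <- vapply(designs, function(d) d$id, character(1))
  write_fasta(seqs, fa)
  tab <- do.call(rbind, lapply(designs, function(d) {
    muts <- if (nrow(d$mutations)) {
      paste0(d$mutations$ref_coord, ":", d$mutations$ref, ">",
             d$mutations$alt, ":", d$mutations$class, collapse = ",")
    } else ""
    data.frame(id = d$id, enzyme = d$enzyme,
               guide = d$guide_id %||% d$pair_id,
               strand = d$strand, length = d$length,
               arm_5 = d$arm_5, arm_3 = d$arm_3,
               mutations = muts,
               blocking_score = d$blocking_score,
               warnings = paste(d$warnings, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, tsv = tsv))
}
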