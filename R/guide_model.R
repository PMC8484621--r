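# Enzyme profiles, PAM scanning on both strands, cut-site geometry,
# edit-to-cut placement classification, guide ranking, and paired-nickase
# enumeration.
#
# Spacer numbering conventions:
#   Cas9:   positions 1..20 from the PAM-distal 5' end; position 20 is
#           PAM-adjacent; the blunt cut falls between positions 17 and 18,
#           i.e. 3 nt 5' of the PAM.
#   Cas12a: positions 1..21 from the PAM-proximal end; position 1 is the
#           first base 3' of the PAM; staggered cuts fall 18 nt (non-target
#           strand) and 23 nt (target strand) from the PAM, leaving a 5-nt
#           5' overhang.

#' Enzyme profile
#'
#' Geometry and recognition parameters for the supported nucleases.
#'
#' @param name `"Cas9"`, `"Cas9-D10A-pair"` or `"Cas12a"`.
#' @return an `enzyme_profile` object.
#' @export
#' @examples
#' enzyme_profile("Cas12a")$pam
enzyme_profile <- function(name = c("Cas9", "Cas9-D10A-pair", "Cas12a")) {
  name <- match.arg(name)
  prof <- switch(name,
    "Cas9" = list(
      name = "Cas9", pam = "NGG", pam_side = "3prime",
      spacer_length = 20L, seed_positions = 9:20,
      cut_offset = 3L,            # nt 5' of the PAM, both strands (blunt)
      indel_window = 8L,
      nickase_pair = FALSE
    ),
    "Cas9-D10A-pair" = list(
      name = "Cas9-D10A-pair", pam = "NGG", pam_side = "3prime",
      spacer_length = 20L, seed_positions = 9:20,
      cut_offset = 3L,
      indel_window = 8L,
      nickase_pair = TRUE
    ),
    "Cas12a" = list(
      name = "Cas12a", pam = "TTTV", pam_side = "5prime",
      spacer_length = 21L,
      cut_offset_nt = 18L,        # non-target strand, nt from the PAM
      cut_offset_t = 23L,         # target strand, nt from the PAM
      indel_window = 9L,
      nickase_pair = FALSE
    )
  )
  structure(prof, class = "enzyme_profile")
}

#' @export
print.enzyme_profile <- function(x, ...) {
  cat(sprintf("<enzyme_profile> %s: PAM %s (%s of protospacer), spacer %d nt\n",
              x$name, x$pam, x$pam_side, x$spacer_length))
  invisible(x)
}

empty_guide_table <- function() {
  structure(
    data.frame(id = character(), enzyme = character(), strand = character(),
               start = integer(), end = integer(),
               pam_start = integer(), pam_end = integer(),
               protospacer = character(), pam = character(),
               cut = integer(), cut_t = integer(),
               stringsAsFactors = FALSE),
    class = c("guide_table", "data.frame"))
}

#' Find all guide sites for an enzyme on both strands
#'
#' Scans the reference for PAM occurrences (IUPAC semantics) on both
#' strands and returns one row per site, ordered by protospacer start
#' coordinate, `+` strand before `-` at ties. `cut` is the blunt-cut
#' boundary for Cas9 and the non-target-strand nick for Cas12a; `cut_t`
#' is the Cas12a target-strand nick (`NA` for Cas9). Sites whose
#' protospacer or cut positions fall outside the reference are dropped.
#'
#' @param ref reference sequence (plus strand).
#' @param enzyme an [enzyme_profile()].
#' @return a `guide_table` data.frame.
#' @export
find_guides <- function(ref, enzyme = enzyme_profile("Cas9")) {
  ref <- dna(ref)
  n <- nchar(ref)
  pam_len <- nchar(enzyme$pam)
  subject <- DNAString(ref)
  plus_hits <- start(matchPattern(enzyme$pam, subject, fixed = FALSE)) - 1L
  minus_pat <- as.character(reverseComplement(DNAString(enzyme$pam)))
  minus_hits <- start(matchPattern(minus_pat, subject, fixed = FALSE)) - 1L

  rows <- list()
  add <- function(strand, pam_start) {
    pam_end <- pam_start + pam_len
    if (enzyme$name %in% c("Cas9", "Cas9-D10A-pair")) {
      if (strand == "+") {
        start <- pam_start - enzyme$spacer_length; end <- pam_start
        cut <- pam_start - enzyme$cut_offset; cut_t <- NA_integer_
      } else {
        start <- pam_end; end <- pam_end + enzyme$spacer_length
        cut <- pam_end + enzyme$cut_offset; cut_t <- NA_integer_
      }
      if (start < 0L || end > n) return()
    } else {
      if (strand == "+") {
        start <- pam_end; end <- pam_end + enzyme$spacer_length
        cut <- pam_end + enzyme$cut_offset_nt
        cut_t <- pam_end + enzyme$cut_offset_t
        if (start < 0L || max(end, cut_t) > n) return()
      } else {
        start <- pam_start - enzyme$spacer_length; end <- pam_start
        cut <- pam_start - enzyme$cut_offset_nt
        cut_t <- pam_start - enzyme$cut_offset_t
        if (min(start, cut_t) < 0L || end > n) return()
      }
    }
    proto <- seq_sub(ref, start, end)
    pam_seq <- seq_sub(ref, pam_start, pam_end)
    if (strand == "-") {
      proto <- revcomp(proto)
      pam_seq <- revcomp(pam_seq)
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      id = sprintf("%s_%s_%d", sub("-.*$", "", tolower(enzyme$name)),
                   if (strand == "+") "p" else "m", start),
      enzyme = enzyme$name, strand = strand,
      start = start, end = end,
      pam_start = pam_start, pam_end = pam_end,
      protospacer = proto, pam = pam_seq,
      cut = as.integer(cut), cut_t = as.integer(cut_t),
      stringsAsFactors = FALSE)
  }
  for (h in plus_hits) add("+", h)
  for (h in minus_hits) add("-", h)
  if (length(rows) == 0L) return(empty_guide_table())
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$start, tab$strand), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("guide_table", "data.frame")
  tab
}

as_guide_row <- function(guide) {
  if (is.data.frame(guide)) {
    if (nrow(guide) != 1L) ssodn_error("expected a single guide (one row)", "ssodn_bounds_error")
    return(as.list(guide))
  }
  if (is.list(guide)) return(guide)
  ssodn_error("guide must be a one-row guide_table or list", "ssodn_bounds_error")
}

#' Cut position(s) of a guide
#'
#' Returns boundary coordinates on the reference: a single blunt-cut
#' coordinate for Cas9 (3 nt 5' of the PAM) or two staggered coordinates
#' for Cas12a, named `nt` (18 nt from the PAM, non-target strand) and `t`
#' (23 nt, target strand).
#'
#' @param guide one row of a [find_guides()] table.
#' @return named integer vector.
#' @export
cut_positions <- function(guide) {
  g <- as_guide_row(guide)
  if (g$enzyme == "Cas12a") c(nt = g$cut, t = g$cut_t) else c(cut = g$cut)
}

# Map a spacer/PAM label ("S14", "P2") to a plus-strand reference
# coordinate for the given guide.
guide_coord <- function(guide, label) {
  g <- as_guide_row(guide)
  type <- substr(label, 1, 1)
  k <- as.integer(substr(label, 2, nchar(label)))
  if (g$enzyme %in% c("Cas9", "Cas9-D10A-pair")) {
    if (type == "S") {
      if (g$strand == "+") g$start + k - 1L else g$start + (20L - k)
    } else {
      if (g$strand == "+") g$pam_start + k - 1L else g$pam_end - k
    }
  } else {
    if (type == "S") {
      if (g$strand == "+") g$pam_end + k - 1L else g$pam_start - k
    } else {
      if (g$strand == "+") g$pam_start + k - 1L else g$pam_end - k
    }
  }
}

#' Map a reference coordinate to a spacer/PAM position label
#'
#' Returns labels such as `"S14"` (spacer position 14) or `"P2"` (PAM
#' position 2) under each enzyme's numbering convention, or `NA` when the
#' coordinate lies outside the protospacer and PAM.
#'
#' @param guide one row of a [find_guides()] table.
#' @param ref_coord 0-based reference coordinate(s).
#' @return character vector of labels (NA outside spacer+PAM).
#' @export
map_guide_position <- function(guide, ref_coord) {
  g <- as_guide_row(guide)
  vapply(ref_coord, function(x) {
    if (x >= g$start && x < g$end) {
      k <- if (g$enzyme %in% c("Cas9", "Cas9-D10A-pair")) {
        if (g$strand == "+") x - g$start + 1L else 20L - (x - g$start)
      } else {
        if (g$strand == "+") x - g$pam_end + 1L else g$pam_start - x
      }
      paste0("S", k)
    } else if (x >= g$pam_start && x < g$pam_end) {
      j <- if (g$strand == "+") x - g$pam_start + 1L else g$pam_end - x
      paste0("P", j)
    } else NA_character_
  }, character(1))
}

# Spacer positions occupied by an edit on a Cas12a guide (lo/hi; for an
# insertion, the boundary position "after spacer position k" is k).
cas12a_spacer_span <- function(guide, edit) {
  g <- as_guide_row(guide)
  if (g$strand == "+") {
    if (edit$start == edit$end) {
      p <- edit$start - g$pam_end
      c(p, p)
    } else {
      c(edit$start - g$pam_end + 1L, edit$end - g$pam_end)
    }
  } else {
    if (edit$start == edit$end) {
      p <- g$pam_start - edit$start
      c(p, p)
    } else {
      c(g$pam_start - edit$end + 1L, g$pam_start - edit$start)
    }
  }
}

boundary_distance <- function(cut, edit) {
  if (edit$start <= cut && cut <= edit$end) return(0L)
  min(abs(cut - edit$start), abs(cut - edit$end))
}

#' Classify the placement of an edit relative to a guide's cut site(s)
#'
#' For Cas9 the side is `at_cut` (distance 0), `PAM_proximal` (the edit is
#' on the PAM-containing side of the cut) or `PAM_distal`. For Cas12a the
#' side is computed relative to the midpoint of the two staggered nicks,
#' and the spacer-position span of the edit is reported together with
#' whether it overlaps the favoured window (spacer positions 12-16).
#' Distances are measured from the nearest cut boundary to the nearest
#' edit boundary.
#'
#' @param guide one row of a [find_guides()] table.
#' @param edit an [edit_spec()].
#' @param window Cas12a favoured spacer-position window, default `c(12, 16)`.
#' @return an `edit_placement` list: `side`, `distance`, `spacer_span`,
#'   `in_spacer_window`.
#' @export
classify_placement <- function(guide, edit, window = c(12L, 16L)) {
  g <- as_guide_row(guide)
  cuts <- cut_positions(g)
  d <- min(vapply(cuts, boundary_distance, integer(1), edit = edit))
  pam_mid <- (g$pam_start + g$pam_end) / 2
  anchor <- mean(cuts)
  edit_mid <- (edit$start + edit$end) / 2
  side <- if (d == 0L) "at_cut"
          else if (sign(edit_mid - anchor) == sign(pam_mid - anchor)) "PAM_proximal"
          else "PAM_distal"
  span <- NULL; in_win <- NA
  if (g$enzyme == "Cas12a") {
    span <- cas12a_spacer_span(g, edit)
    in_win <- span[2] >= window[1] && span[1] <= window[2]
  }
  structure(list(side = side, distance = as.integer(d),
                 spacer_span = span, in_spacer_window = in_win,
                 guide_id = g$id),
            class = "edit_placement")
}

# Does the edit overlap the protospacer or PAM of a guide?
edit_hits_protospacer <- function(guide, edit) {
  g <- as_guide_row(guide)
  lo <- min(g$start, g$pam_start); hi <- max(g$end, g$pam_end)
  if (edit$start == edit$end) edit$start > lo && edit$start < hi
  else edit$start < hi && edit$end > lo
}

#' Rank guides for an HDR edit
#'
#' Keeps guides whose nearest cut is within `max_distance` of the edit and
#' sorts them by activity (descending, when supplied), then distance
#' (ascending), then coordinate. Guide efficiency dominates proximity:
#' a distant, highly active guide outranks a close, weak one. Without
#' activity scores, distance alone is used.
#'
#' @param guides a [find_guides()] table.
#' @param edit an [edit_spec()].
#' @param max_distance maximum edit-to-cut distance in nt (default 15).
#' @param activity optional numeric vector of per-guide activities in
#'   `[0, 1]`, either named by guide id or parallel to `guides`.
#' @return the filtered, ordered guide table with `distance`, `side` and
#'   `activity` columns; attribute `diagnostic` is set when empty.
#' @export
rank_guides <- function(guides, edit, max_distance = 15L, activity = NULL) {
  if (max_distance <= 0L) ssodn_error("max_distance must be > 0", "ssodn_bounds_error")
  if (nrow(guides) == 0L) {
    out <- guides
    attr(out, "diagnostic") <- "no guide sites found"
    return(out)
  }
  pl <- lapply(seq_len(nrow(guides)),
               function(i) classify_placement(guides[i, ], edit))
  guides$distance <- vapply(pl, function(p) p$distance, integer(1))
  guides$side <- vapply(pl, function(p) p$side, character(1))
  if (!is.null(activity)) {
    act <- if (!is.null(names(activity))) unname(activity[guides$id])
           else if (length(activity) == nrow(guides)) as.numeric(activity)
           else ssodn_error("activity must be named by guide id or parallel to guides",
                            "ssodn_bounds_error")
    guides$activity <- act
  } else {
    guides$activity <- NA_real_
  }
  keep <- guides$distance <= max_distance
  out <- guides[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    attr(out, "diagnostic") <- paste0(
      "no guide cut within ", max_distance, " nt of the edit; ",
      "consider a paired-nickase (design_nickase) or Cas12a (design_cas12a) design")
    return(out)
  }
  a <- out$activity
  ord <- order(is.na(a), -ifelse(is.na(a), 0, a), out$distance, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate valid paired-nickase (Cas9 D10A) designs
#'
#' Pairs of Cas9 guides on opposite strands in PAM-out orientation (both
#' PAMs outside the inter-nick interval) whose nick-to-nick spacing lies
#' within `[spacing_min, spacing_max]` (defaults 40-68 nt) and, when an
#' edit is supplied, whose inter-nick interval fully contains the edit.
#' Spacing below the 35-nt floor (where editing is poor) is refused unless
#' `force = TRUE`. PAM-in pairs are only listed with
#' `include_pam_in = TRUE` and are marked not recommended.
#'
#' @param ref reference sequence.
#' @param edit optional [edit_spec()] that must lie between the nicks.
#' @param spacing_min,spacing_max inclusive nick-spacing bounds.
#' @param include_pam_in also list PAM-in pairs (marked not recommended).
#' @param force allow `spacing_min` below the 35-nt floor.
#' @return a `nickase_pair_table` data.frame; attribute `diagnostic` is
#'   set when empty.
#' @export
find_nickase_pairs <- function(ref, edit = NULL, spacing_min = 40L,
                               spacing_max = 68L, include_pam_in = FALSE,
                               force = FALSE) {
  if (spacing_min >= spacing_max) {
    ssodn_error("spacing_min must be < spacing_max", "ssodn_bounds_error")
  }
  if (spacing_min < 35L && !force) {
    ssodn_warning("spacing_min below the 35-nt floor raised to 35 (use force = TRUE to override)")
    spacing_min <- 35L
  }
  guides <- find_guides(ref, enzyme_profile("Cas9-D10A-pair"))
  empty <- structure(
    data.frame(pair_id = character(), left_id = character(),
               right_id = character(), orientation = character(),
               nick_left = integer(), nick_right = integer(),
               spacing = integer(), recommended = logical(),
               stringsAsFactors = FALSE),
    class = c("nickase_pair_table", "data.frame"))
  plus <- guides[guides$strand == "+", , drop = FALSE]
  minus <- guides[guides$strand == "-", , drop = FALSE]
  rows <- list()
  seen_pam_in <- FALSE
  for (i in seq_len(nrow(minus))) {
    for (j in seq_len(nrow(plus))) {
      gm <- minus[i, ]; gp <- plus[j, ]
      # orientation from which guide carries the left nick
      if (gm$cut < gp$cut) {
        left <- gm; right <- gp; orientation <- "PAM-out"
      } else if (gp$cut < gm$cut) {
        left <- gp; right <- gm; orientation <- "PAM-in"
      } else next
      spacing <- right$cut - left$cut
      if (spacing < spacing_min || spacing > spacing_max) next
      if (orientation == "PAM-in") {
        seen_pam_in <- TRUE
        if (!include_pam_in) next
      }
      if (!is.null(edit)) {
        inside <- edit$start >= left$cut && edit$end <= right$cut
        if (!inside) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = sprintf("pair_%d_%d", left$cut, right$cut),
        left_id = left$id, right_id = right$id,
        orientation = orientation,
        nick_left = left$cut, nick_right = right$cut,
        spacing = spacing,
        recommended = orientation == "PAM-out",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    out <- empty
    attr(out, "diagnostic") <- if (seen_pam_in && !include_pam_in) {
      "only PAM-in pairs available in the spacing window; PAM-out orientation is required for efficient nickase editing"
    } else {
      "no guide pair with PAM-out orientation and 40-68 nt nick spacing spans the edit"
    }
    attr(out, "guides") <- guides
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$nick_left, out$nick_right), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nickase_pair_table", "data.frame")
  attr(out, "guides") <- guides
  out
}

as_pair_row <- function(pair) {
  if (is.data.frame(pair)) {
    if (nrow(pair) != 1L) ssodn_error("expected a single pair (one row)", "ssodn_bounds_error")
    return(as.list(pair))
  }
  pair
}

#' Export guides or nickase pairs as TSV
#'
#' @param x a `guide_table` or `nickase_pair_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_guides_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
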