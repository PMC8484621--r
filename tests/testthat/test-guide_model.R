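# PAM scanning, cut geometry, placement classification, guide ranking,
# and paired-nickase enumeration.

test_that("find_guides recovers a planted plus-strand Cas9 site with correct geometry", {
  set.seed(9)
  bg <- paste0(sample(c("A", "C", "T"), 300, TRUE), collapse = "")
  ref <- paste0(substr(bg, 1, 120), "AGG", substr(bg, 124, 300))
  g <- find_guides(ref, enzyme_profile("Cas9"))
  hit <- g[g$strand == "+" & g$pam_start == 120, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 100L)
  expect_identical(hit$end, 120L)
  expect_identical(hit$pam, "AGG")
  expect_identical(hit$cut, 117L)  # blunt cut 3 nt 5' of the PAM
})

test_that("a G/C-free sequence has no Cas9 sites and an AT-free locus no Cas12a sites", {
  set.seed(3)
  at_only <- paste0(sample(c("A", "T"), 500, TRUE), collapse = "")
  expect_identical(nrow(find_guides(at_only, enzyme_profile("Cas9"))), 0L)
  gc_only <- paste0(sample(c("G", "C"), 500, TRUE), collapse = "")
  expect_identical(nrow(find_guides(gc_only, enzyme_profile("Cas12a"))), 0L)
})

test_that("find_guides equals the brute-force IUPAC scan oracle on random sequences", {
  set.seed(77)
  for (i in 1:15) {
    ref <- random_seq(1000)
    got <- find_guides(ref, enzyme_profile("Cas9"))
    want <- oracle_find_guides_cas9(ref)
    got_plus <- got[got$strand == "+", ]
    want_plus <- want[want$strand == "+", ]
    expect_setequal(got_plus$pam_start, want_plus$pam_start)
    got_minus <- got[got$strand == "-", ]
    want_minus <- want[want$strand == "-", ]
    expect_setequal(got_minus$pam_start, want_minus$pam_start)
    # geometry agrees site by site
    m <- merge(as.data.frame(got), want, by = c("strand", "pam_start"))
    expect_identical(nrow(m), nrow(got))
    expect_identical(m$start.x, m$start.y)
    expect_identical(m$cut.x, m$cut.y)
  }
})

test_that("guide discovery is strand-symmetric under reverse complement", {
  set.seed(5150)
  for (i in 1:10) {
    ref <- random_seq(600)
    L <- nchar(ref)
    fwd <- find_guides(ref, enzyme_profile("Cas9"))
    rev <- find_guides(revcomp(ref), enzyme_profile("Cas9"))
    # mirror: plus sites map to minus sites with reflected coordinates
    expect_identical(nrow(fwd), nrow(rev))
    mirrored_cuts <- sort(L - rev$cut)
    expect_identical(sort(fwd$cut), mirrored_cuts)
    mirrored_pams <- sort(L - rev$pam_end)
    expect_identical(sort(fwd$pam_start), mirrored_pams)
  }
})

test_that("Cas12a staggered cuts sit 18 and 23 nt from the PAM with a 5-nt 5' overhang", {
  set.seed(2)
  bg <- paste0(sample(c("A", "C", "G"), 400, TRUE), collapse = "")
  ref <- paste0(substr(bg, 1, 150), "TTTC", substr(bg, 155, 400))
  g <- find_guides(ref, enzyme_profile("Cas12a"))
  hit <- g[g$strand == "+" & g$pam_start == 150, ]
  expect_identical(nrow(hit), 1L)
  cuts <- cut_positions(hit)
  expect_identical(unname(cuts["nt"] - hit$pam_end), 18L)
  expect_identical(unname(cuts["t"] - hit$pam_end), 23L)
  expect_identical(unname(cuts["t"] - cuts["nt"]), 5L)  # 5' overhang
  # minus strand mirror
  ref_rc <- revcomp(ref)
  g2 <- find_guides(ref_rc, enzyme_profile("Cas12a"))
  hit2 <- g2[g2$strand == "-", ]
  hit2 <- hit2[hit2$pam_end == nchar(ref) - 150, ]
  expect_identical(nrow(hit2), 1L)
  cuts2 <- cut_positions(hit2)
  expect_identical(unname(hit2$pam_start - cuts2["nt"]), 18L)
  expect_identical(unname(hit2$pam_start - cuts2["t"]), 23L)
})

test_that("cut coordinates reflect under reverse complement (minus-strand mirror case)", {
  set.seed(12)
  locus <- toy_cas9_locus(12, 300, 150)
  ref <- locus$sequence[[1]]
  L <- nchar(ref)
  g <- find_guides(ref, enzyme_profile("Cas9"))
  site <- g[g$strand == "+" & g$pam_start == 150, ]
  grc <- find_guides(revcomp(ref), enzyme_profile("Cas9"))
  mirror <- grc[grc$strand == "-" & grc$pam_end == L - 150, ]
  expect_identical(nrow(mirror), 1L)
  expect_identical(mirror$cut, L - site$cut)
})

test_that("placement classification: at-cut, PAM-proximal, PAM-distal, distances", {
  locus <- toy_cas9_locus(21, 300, 150)
  ref <- locus$sequence[[1]]
  g <- find_guides(ref, enzyme_profile("Cas9"))
  gw <- g[g$strand == "+" & g$pam_start == 150, ]
  cut <- gw$cut  # 147
  p0 <- classify_placement(gw, edit_spec(cut, cut, "GAATTC"))
  expect_identical(p0$side, "at_cut")
  expect_identical(p0$distance, 0L)
  # insertion 20 nt beyond the PAM (PAM side)
  p1 <- classify_placement(gw, edit_spec(cut + 20, cut + 20, "GAATTC"))
  expect_identical(p1$side, "PAM_proximal")
  expect_identical(p1$distance, 20L)
  # non-PAM side
  p2 <- classify_placement(gw, edit_spec(cut - 25, cut - 25, "GAATTC"))
  expect_identical(p2$side, "PAM_distal")
  expect_identical(p2$distance, 25L)
})

test_that("Cas12a spacer span maps edits to guide positions (window 12-16)", {
  set.seed(8)
  spec <- sim_spec(seed = 8, locus_length = 400, tttv_pam_plus = 150)
  ref <- make_toy_locus(spec)$sequence[[1]]
  g <- find_guides(ref, enzyme_profile("Cas12a"))
  gw <- g[g$strand == "+" & g$pam_start == 150, ]
  # insertion at spacer position 15 (boundary pam_end + 15)
  p15 <- classify_placement(gw, edit_spec(154 + 15, 154 + 15, "GAATTC"))
  expect_true(p15$in_spacer_window)
  expect_identical(p15$spacer_span, c(15L, 15L))
  # position 24: outside the protospacer
  p24 <- classify_placement(gw, edit_spec(154 + 24, 154 + 24, "GAATTC"))
  expect_false(p24$in_spacer_window)
  # position 5: inside protospacer, outside window
  p5 <- classify_placement(gw, edit_spec(154 + 5, 154 + 5, "GAATTC"))
  expect_false(p5$in_spacer_window)
})

test_that("rank_guides puts activity above proximity, falls back to distance, and diagnoses empty results", {
  locus <- toy_cas9_locus(31, 400, 200)
  ref <- locus$sequence[[1]]
  g <- find_guides(ref, enzyme_profile("Cas9"))
  edit <- edit_spec(197, 197, "GAATTC")
  ranked <- rank_guides(g, edit, max_distance = 20)
  expect_true(nrow(ranked) >= 1)
  expect_true(all(diff(ranked$distance) >= 0))  # distance order without activity
  if (nrow(ranked) >= 2) {
    # the distant guide with high activity outranks the near weak one
    act <- setNames(rep(0.1, nrow(ranked)), ranked$id)
    act[ranked$id[nrow(ranked)]] <- 0.96  # farthest guide, high activity
    act[ranked$id[1]] <- 0.32             # nearest guide, weak
    r2 <- rank_guides(g, edit, max_distance = 20, activity = act)
    expect_identical(r2$id[1], ranked$id[nrow(ranked)])
  }
  r3 <- rank_guides(g, edit, max_distance = 1)
  if (nrow(r3) == 0) expect_match(attr(r3, "diagnostic"), "nickase|Cas12a")
  expect_error(rank_guides(g, edit, max_distance = 0), class = "ssodn_bounds_error")
})

test_that("nickase pairs: PAM-out only, spacing bounds inclusive, edit between nicks", {
  spec <- sim_spec(seed = 7, locus_length = 400, pair = list(left_cut = 150, spacing = 46))
  ref <- make_toy_locus(spec)$sequence[[1]]
  edit_mid <- edit_spec(170, 170, "GAATTC")
  pairs <- find_nickase_pairs(ref, edit_mid)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$spacing, 46L)
  expect_identical(pairs$orientation, "PAM-out")
  expect_identical(pairs$nick_left, 150L)
  expect_identical(pairs$nick_right, 196L)
  # edit outside the inter-nick interval is rejected
  edit_out <- edit_spec(208, 208, "GAATTC")  # 12 nt beyond the right nick
  expect_identical(nrow(find_nickase_pairs(ref, edit_out)), 0L)
  # spacing window is inclusive at both ends and rejects outside values
  for (sp in c(40L, 68L)) {
    r <- make_toy_locus(sim_spec(seed = 7, locus_length = 400,
                                 pair = list(left_cut = 150, spacing = sp)))
    e <- edit_spec(150 + sp %/% 2, 150 + sp %/% 2, "GAATTC")
    expect_identical(nrow(find_nickase_pairs(r$sequence[[1]], e)), 1L,
                     info = paste("spacing", sp))
  }
  for (sp in c(39L, 69L, 85L)) {
    r <- make_toy_locus(sim_spec(seed = 7, locus_length = 400,
                                 pair = list(left_cut = 150, spacing = sp)))
    e <- edit_spec(150 + sp %/% 2, 150 + sp %/% 2, "GAATTC")
    expect_identical(nrow(find_nickase_pairs(r$sequence[[1]], e)), 0L,
                     info = paste("spacing", sp))
  }
})

test_that("PAM-in pairs are rejected by default and flagged when requested", {
  spec <- sim_spec(seed = 13, locus_length = 400,
                   pair = list(left_cut = 150, spacing = 50, orientation = "in"))
  ref <- make_toy_locus(spec)$sequence[[1]]
  e <- edit_spec(175, 175, "GAATTC")
  res <- find_nickase_pairs(ref, e)
  expect_identical(nrow(res), 0L)
  expect_match(attr(res, "diagnostic"), "PAM")
  res2 <- find_nickase_pairs(ref, e, include_pam_in = TRUE)
  expect_true(nrow(res2) >= 1)
  expect_true(all(res2$orientation == "PAM-in"))
  expect_true(all(!res2$recommended))
})

test_that("spacing floor at 35 nt is enforced unless forced", {
  spec <- sim_spec(seed = 19, locus_length = 400, pair = list(left_cut = 150, spacing = 32))
  ref <- make_toy_locus(spec)$sequence[[1]]
  e <- edit_spec(166, 166, "GAATTC")
  expect_warning(res <- find_nickase_pairs(ref, e, spacing_min = 30),
                 class = "ssodn_warning")
  expect_identical(nrow(res), 0L)
  res2 <- find_nickase_pairs(ref, e, spacing_min = 30, force = TRUE)
  expect_identical(nrow(res2), 1L)
  expect_identical(res2$spacing, 32L)
})

test_that("every returned pair satisfies the pair invariants on generated loci", {
  set.seed(404)
  for (i in 1:8) {
    sp <- sample(40:68, 1)
    spec <- sim_spec(seed = 404 + i, locus_length = 450,
                     pair = list(left_cut = 160, spacing = sp))
    ref <- make_toy_locus(spec)$sequence[[1]]
    e <- edit_spec(160 + sp %/% 2, 160 + sp %/% 2, "GAATTC")
    pairs <- find_nickase_pairs(ref, e)
    guides <- attr(pairs, "guides")
    for (j in seq_len(nrow(pairs))) {
      p <- pairs[j, ]
      left <- guides[guides$id == p$left_id, ]
      right <- guides[guides$id == p$right_id, ]
      expect_true(left$strand != right$strand)
      expect_identical(p$orientation, "PAM-out")
      expect_true(p$spacing >= 40 && p$spacing <= 68)
      expect_true(e$start >= p$nick_left && e$end <= p$nick_right)
      # PAM-out means both PAMs outside the inter-nick interval
      expect_true(left$pam_end <= p$nick_left + 3)
      expect_true(left$pam_start < p$nick_left)
      expect_true(right$pam_start >= p$nick_right)
    }
  }
})
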