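# Strand choice, repair-track mutations, donor assembly, and the three
# enzyme-specific design flows.

# Apply a donor back onto the reference and return the plus-strand allele
# it encodes, independently of build_donor's internals.
expected_allele <- function(ref, edit, mutations) {
  chars <- strsplit(ref, "")[[1]]
  for (i in seq_len(nrow(mutations))) {
    chars[mutations$ref_coord[i] + 1L] <- mutations$alt[i]
  }
  s <- paste0(chars, collapse = "")
  paste0(substr(s, 1, edit$start), edit$replacement,
         substr(s, edit$end + 1, nchar(s)))
}

test_that("choose_strand implements the full enzyme x placement rule table", {
  cfg <- design_config()
  cas9 <- enzyme_profile("Cas9")
  mk <- function(side, dist) structure(list(side = side, distance = dist),
                                       class = "edit_placement")
  expect_identical(choose_strand(cas9, mk("PAM_proximal", 25), cfg)$strand, "T")
  expect_identical(choose_strand(cas9, mk("PAM_proximal", 20), cfg)$strand, "T")
  expect_identical(choose_strand(cas9, mk("PAM_distal", 20), cfg)$strand, "NT")
  expect_identical(choose_strand(cas9, mk("PAM_distal", 25), cfg)$strand, "NT")
  at <- choose_strand(cas9, mk("at_cut", 0), cfg)
  expect_identical(at$strand, "NT")
  expect_match(at$rationale, "cell-type")
  # near-cut edits take the configured default regardless of side
  expect_identical(choose_strand(cas9, mk("PAM_proximal", 5), cfg)$strand, "NT")
  expect_identical(choose_strand(cas9, mk("PAM_proximal", 5),
                                 design_config(strand_at_cut = "T"))$strand, "T")
  expect_identical(choose_strand(enzyme_profile("Cas9-D10A-pair"),
                                 mk("at_cut", 0), cfg)$strand, "both")
  for (side in c("at_cut", "PAM_proximal", "PAM_distal")) {
    expect_identical(choose_strand(enzyme_profile("Cas12a"),
                                   mk(side, 20), cfg)$strand, "NT")
  }
})

test_that("repair track: 25-nt non-coding track gets 4 mutations every 5 nt; short tracks none", {
  locus <- toy_cas9_locus(111, 320, 160)
  ref <- locus$sequence[[1]]
  g <- find_guides(ref, enzyme_profile("Cas9"))
  gw <- g[g$strand == "+" & g$pam_start == 160, ]
  cut <- gw$cut
  edit <- edit_spec(cut - 25, cut - 25, "GAATTC")  # PAM-distal, 25 nt
  muts <- repair_track_mutations(ref, gw, edit, NULL, design_config())
  expect_identical(nrow(muts), 4L)
  expect_true(all(muts$class == "repair_track"))
  d <- sort(cut - 1 - muts$ref_coord)
  expect_equal(d, c(5, 10, 15, 20), ignore_attr = TRUE)
  # transversions only in non-coding mode
  expect_true(all(paste0(muts$ref, muts$alt) %in% c("AC", "CA", "GT", "TG")))
  # at or below the trigger distance: no track mutations
  near <- edit_spec(cut - 8, cut - 8, "GAATTC")
  expect_identical(nrow(repair_track_mutations(ref, gw, near, NULL, design_config())), 0L)
})

test_that("coding repair tracks slide to synonymous positions and never change the protein", {
  set.seed(222)
  n_with <- 0L
  for (i in 1:25) {
    locus <- toy_cas9_locus(600 + i, 340, 170)
    ref <- locus$sequence[[1]]
    g <- find_guides(ref, enzyme_profile("Cas9"))
    gw <- g[g$strand == "+" & g$pam_start == 170, ]
    if (nrow(gw) != 1) next
    cut <- gw$cut
    ann <- coding_annotation(data.frame(start = cut - 30, end = cut + 3), "+", i %% 3)
    edit <- edit_spec(cut - 25, cut - 25, "GAATTC")
    muts <- repair_track_mutations(ref, gw, edit, ann, design_config())
    if (nrow(muts) > 0) n_with <- n_with + 1L
    for (j in seq_len(nrow(muts))) {
      mu <- muts[j, ]
      expect_true(as.logical(is_synonymous(ref, ann, mu$ref_coord, mu$alt)))
    }
    # protein is unchanged after applying all track mutations
    mutated <- ref
    for (j in seq_len(nrow(muts))) {
      substr(mutated, muts$ref_coord[j] + 1, muts$ref_coord[j] + 1) <- muts$alt[j]
    }
    expect_identical(translate_cds(mutated, ann), translate_cds(ref, ann))
  }
  expect_gt(n_with, 10L)
})

test_that("a 6-nt insertion at the cut with 40-nt arms yields an 86-nt donor; T/NT are reverse complements", {
  locus <- toy_cas9_locus(131, 300, 150)
  ref <- locus$sequence[[1]]
  g <- find_guides(ref, enzyme_profile("Cas9"))
  gw <- g[g$strand == "+" & g$pam_start == 150, ]
  edit <- edit_spec(gw$cut, gw$cut, "GAATTC")
  d_nt <- build_donor(ref, guide = gw, edit = edit, strand = "NT")
  expect_identical(d_nt$length, 86L)
  expect_identical(d_nt$arm_5, 40L)
  expect_identical(d_nt$arm_3, 40L)
  d_t <- build_donor(ref, guide = gw, edit = edit, strand = "T")
  expect_identical(revcomp(d_nt$sequence), d_t$sequence)
  # the NT donor matches the expected allele slice
  allele <- expected_allele(ref, edit, mutation_set())
  expect_identical(d_nt$sequence, substr(allele, gw$cut - 40 + 1, gw$cut + 6 + 40))
})

test_that("donor validation: 200-nt cap, excess named, arm floor with override", {
  locus <- toy_cas9_locus(141, 400, 200)
  ref <- locus$sequence[[1]]
  g <- find_guides(ref, enzyme_profile("Cas9"))
  gw <- g[g$strand == "+" & g$pam_start == 200, ]
  cut <- gw$cut
  # 121-nt insertion at 40-nt arms -> 201 nt -> length error
  big <- edit_spec(cut, cut, random_seq(121))
  expect_error(build_donor(ref, guide = gw, edit = big, strand = "NT"),
               class = "ssodn_length_error")
  # 160-nt insertion at 20-nt arms -> exactly 200 nt -> accepted (with arm warning)
  cfg20 <- design_config(allow_short_arms = TRUE)
  ins160 <- edit_spec(cut, cut, random_seq(160))
  d <- build_donor(ref, guide = gw, edit = ins160, strand = "NT",
                   config = cfg20, arm_5 = 20, arm_3 = 20)
  expect_identical(d$length, 200L)
  expect_true(any(grepl("floor", d$warnings)))
  # 161-nt insertion at the same minimum arms -> length error
  ins161 <- edit_spec(cut, cut, random_seq(161))
  expect_error(build_donor(ref, guide = gw, edit = ins161, strand = "NT",
                           config = cfg20, arm_5 = 20, arm_3 = 20),
               class = "ssodn_length_error")
  # arms below the floor are refused without the override
  expect_error(build_donor(ref, guide = gw, edit = edit_spec(cut, cut, "GAATTC"),
                           strand = "NT", arm_5 = 20, arm_3 = 20),
               class = "ssodn_arm_error")
  # allow_long lifts the cap
  d2 <- build_donor(ref, guide = gw, edit = big, strand = "NT",
                    config = design_config(allow_long = TRUE))
  expect_identical(d2$length, 201L)
})

test_that("design_cas9 rule table: at-cut, PAM-distal and PAM-proximal flows", {
  locus <- toy_cas9_locus(151, 400, 200)
  ref <- locus$sequence[[1]]
  g <- find_guides(ref, enzyme_profile("Cas9"))
  gw <- g[g$strand == "+" & g$pam_start == 200, ]
  cut <- gw$cut
  # substitution just beyond the PAM: near-cut -> {P2,P3}, NT default strand
  refb <- ssodn:::seq_base(ref, 206)
  near <- edit_spec(206, 207, setdiff(c("A", "C", "G", "T"), refb)[1])
  designs <- design_cas9(ref, near)
  expect_gt(length(designs), 0)
  top <- designs[[1]]
  expect_identical(top$strand, "NT")
  expect_setequal(top$mutations$pos_label, c("P2", "P3"))
  expect_identical(top$blocking_score, 1.97)
  # PAM-distal 20-nt: NT strand, track mutations, no PAM mutation
  distal <- edit_spec(cut - 20, cut - 20, "GAATTC")
  dd <- design_cas9(ref, distal, config = design_config(max_guide_distance = 25))
  expect_gt(length(dd), 0)
  top_d <- dd[[1]]
  expect_identical(top_d$strand, "NT")
  expect_true(all(top_d$mutations$class == "repair_track"))
  expect_false(any(grepl("^P", top_d$mutations$pos_label)))
  # PAM-proximal 20-nt: T strand, one PAM mutation plus track mutations
  prox <- edit_spec(cut + 20, cut + 20, "GAATTC")
  dp <- design_cas9(ref, prox, config = design_config(max_guide_distance = 25))
  expect_gt(length(dp), 0)
  top_p <- dp[[1]]
  expect_identical(top_p$strand, "T")
  expect_identical(sum(top_p$mutations$class == "blocking_PAM"), 1L)
  expect_gt(sum(top_p$mutations$class == "repair_track"), 0L)
  # no guide in range -> diagnostic pointing at the other enzymes
  far <- edit_spec(30, 30, "GAATTC")
  empty <- design_cas9(ref, far, config = design_config(max_guide_distance = 5))
  expect_identical(length(empty), 0L)
  expect_match(attr(empty, "diagnostic"), "nickase|Cas12a")
})

test_that("design_nickase emits top+bottom donors, no blocking mutations, edit between nicks", {
  spec <- sim_spec(seed = 7, locus_length = 400, pair = list(left_cut = 150, spacing = 46))
  ref <- make_toy_locus(spec)$sequence[[1]]
  edit <- edit_spec(173, 173, "GAATTC")
  designs <- design_nickase(ref, edit)
  expect_identical(length(designs), 2L)
  expect_setequal(vapply(designs, function(d) d$strand, character(1)),
                  c("top", "bottom"))
  for (d in designs) {
    expect_identical(nrow(d$mutations), 0L)
    expect_identical(d$enzyme, "Cas9-D10A-pair")
  }
  expect_identical(revcomp(designs[[1]]$sequence), designs[[2]]$sequence)
  # arms beyond both nicks: the donor must span [nick_left-40, nick_right+40)
  d <- designs[[1]]
  expect_lte(d$donor_ref_start, 150 - 40)
  expect_gte(d$donor_ref_end, 196 + 40)
  # edit outside the inter-nick interval -> no designs
  out <- design_nickase(ref, edit_spec(208, 208, "GAATTC"))
  expect_identical(length(out), 0L)
  expect_true(nzchar(attr(out, "diagnostic")))
  # PAM-in-only locus -> no designs with orientation diagnostic
  spec_in <- sim_spec(seed = 13, locus_length = 400,
                      pair = list(left_cut = 150, spacing = 50, orientation = "in"))
  ref_in <- make_toy_locus(spec_in)$sequence[[1]]
  res_in <- design_nickase(ref_in, edit_spec(175, 175, "GAATTC"))
  expect_identical(length(res_in), 0L)
  expect_match(attr(res_in, "diagnostic"), "PAM")
})

test_that("design_cas12a: in-window edits rank first with zero blocking; outside-protospacer edits get exactly one", {
  spec <- sim_spec(seed = 11, locus_length = 400, tttv_pam_plus = 150)
  ref <- make_toy_locus(spec)$sequence[[1]]
  pam_end <- 154
  # position 15 (in the favoured 12-16 window)
  d15 <- design_cas12a(ref, edit_spec(pam_end + 15, pam_end + 15, "GAATTC"))
  expect_gt(length(d15), 0)
  expect_identical(d15[[1]]$strand, "NT")
  expect_identical(nrow(d15[[1]]$mutations), 0L)
  # position 24 (outside the protospacer): one blocking mutation, PAM TVTV here
  d24 <- design_cas12a(ref, edit_spec(pam_end + 24, pam_end + 24, "GAATTC"))
  expect_gt(length(d24), 0)
  expect_identical(nrow(d24[[1]]$mutations), 1L)
  expect_identical(d24[[1]]$mutations$pos_label, "P2")
  expect_identical(d24[[1]]$mutations$ref, "T")
  expect_true(d24[[1]]$mutations$alt %in% c("A", "C", "G"))
  # with a coding annotation, the blocking mutation is a synonymous
  # protospacer option near position 14 instead
  ann <- coding_annotation(data.frame(start = 140, end = 185), "+", 0)
  d24c <- design_cas12a(ref, edit_spec(pam_end + 24, pam_end + 24, "GAATTC"),
                        annotation = ann)
  expect_gt(length(d24c), 0)
  mu <- d24c[[1]]$mutations
  expect_identical(nrow(mu), 1L)
  if (grepl("^S", mu$pos_label)) {
    expect_true(as.logical(is_synonymous(ref, ann, mu$ref_coord, mu$alt)))
  }
  # AT-free locus: no TTTV -> diagnostic
  set.seed(1)
  gc_only <- paste0(sample(c("G", "C"), 400, TRUE), collapse = "")
  none <- design_cas12a(gc_only, edit_spec(200, 200, "GAATTC"))
  expect_identical(length(none), 0L)
  expect_match(attr(none, "diagnostic"), "TTTV")
})

test_that("round-trip invariant: every emitted donor encodes exactly the edit plus its recorded mutations", {
  set.seed(1001)
  checked <- 0L
  for (i in 1:40) {
    locus <- toy_cas9_locus(3000 + i, 360, 180)
    ref <- locus$sequence[[1]]
    g <- find_guides(ref, enzyme_profile("Cas9"))
    gw <- g[g$strand == "+" & g$pam_start == 180, ]
    if (nrow(gw) != 1) next
    cut <- gw$cut
    kind <- i %% 3
    edit <- if (kind == 0) edit_spec(cut, cut, "GAATTC")
            else if (kind == 1) edit_spec(cut - 20, cut - 20, "GAATTC")
            else edit_spec(cut + 18, cut + 18, "GAATTC")
    designs <- design_cas9(ref, edit, config = design_config(max_guide_distance = 25))
    for (d in designs) {
      allele <- expected_allele(ref, d$edit, d$mutations)
      core <- substr(allele, d$donor_ref_start + 1,
                     d$donor_ref_end + nchar(d$edit$replacement) -
                       (d$edit$end - d$edit$start))
      want <- if (d$strand %in% c("T", "bottom")) revcomp(core) else core
      expect_identical(d$sequence, want)
      expect_lte(d$blocking_score, 1.97 + 1e-12)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 25L)
})

test_that("arm invariant holds across random loci and edits", {
  set.seed(77)
  for (i in 1:30) {
    locus <- toy_cas9_locus(4000 + i, 400, 200)
    ref <- locus$sequence[[1]]
    g <- find_guides(ref, enzyme_profile("Cas9"))
    gw <- g[g$strand == "+" & g$pam_start == 200, ]
    if (nrow(gw) != 1) next
    offset <- sample(-12:12, 1)
    edit <- edit_spec(gw$cut + offset, gw$cut + offset, "GAATTC")
    designs <- design_cas9(ref, edit, config = design_config(max_guide_distance = 20))
    for (d in designs) {
      expect_gte(min(d$arm_5, d$arm_3), 30)
      own_guide <- g[g$id == d$guide_id, ]
      bounds <- c(unname(cut_positions(own_guide)), d$edit$start, d$edit$end,
                  d$mutations$ref_coord)
      expect_lte(d$donor_ref_start, min(bounds) - d$arm_5)
      expect_gte(d$donor_ref_end, max(bounds) + d$arm_3)
    }
  }
})

test_that("designs and their TSV/FASTA exports round-trip through the readers", {
  locus <- toy_cas9_locus(555, 300, 150)
  ref <- locus$sequence[[1]]
  edit <- edit_spec(147, 147, "GAATTC", "ins")
  designs <- design_cas9(ref, edit)
  prefix <- file.path(withr::local_tempdir(), "designs")
  write_designs(designs, prefix)
  fa <- read_locus_fasta(paste0(prefix, ".fasta"))
  expect_identical(length(fa), length(designs))
  expect_identical(unname(fa[1]), designs[[1]]$sequence)
  tab <- read.delim(paste0(prefix, ".tsv"))
  expect_identical(nrow(tab), length(designs))
  expect_identical(tab$length[1], designs[[1]]$length)
})
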