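---
title: "Designing ssODN donor templates for CRISPR HDR"
author: "ssodn package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing ssODN donor templates for CRISPR HDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssodn)
```

## The problem

Homology-directed repair (HDR) lets a CRISPR nuclease introduce a precise
edit — a point mutation, an epitope tag, a restriction site — from a
single-stranded oligodeoxynucleotide (ssODN) donor. HDR competes with the
faster, error-prone non-homologous end joining (NHEJ) pathway, and the
repaired allele can be re-cut if the protospacer and PAM survive the edit.
In practice HDR efficiency is dominated by a small set of design choices:
which guide to use, which strand of the donor to synthesise, where the edit
sits relative to the cut, and which additional "blocking" mutations the
donor carries to prevent re-cleavage. This package encodes an empirically
derived ruleset for those choices for three enzymes — *S. pyogenes* Cas9,
paired Cas9 D10A nickases, and *A. s.* Cas12a — together with an amplicon
read classifier for quantifying the editing outcome and a simulator that
makes the whole pipeline testable without any external data.

All coordinates are 0-based and half-open on the plus strand of the
supplied reference; cut positions are boundary coordinates (a cut at `c`
falls between base `c - 1` and base `c`).

## Enzyme geometry

* **Cas9** recognises an `NGG` PAM 3' of a 20-nt protospacer and cuts
  bluntly 3 nt 5' of the PAM (between spacer positions 17 and 18; spacer
  positions are numbered 1–20 from the PAM-distal end). The seed region —
  where mismatches most strongly abolish cleavage — is taken as the
  PAM-proximal 12 positions.
* **Cas9 D10A** nicks only the target strand; a pair of guides on opposite
  strands creates a staggered break. Editing is efficient only for PAM-out
  orientation (both PAMs pointing away from the inter-nick interval) with
  nick-to-nick spacing of 40–68 nt, and the edit is best placed between the
  nicks. Spacings below 35 nt edit poorly and are refused unless forced.
  The measurement convention (nick-to-nick) is a package choice; the
  spacing bounds are configurable.
* **Cas12a** recognises a 5' `TTTV` PAM and makes a staggered cut 18 nt
  (non-target strand) and 23 nt (target strand) from the PAM, leaving a
  5-nt 5' overhang. Spacer positions are numbered 1–21 from the first base
  3' of the PAM. HDR insertions work best at spacer positions 12–16, a
  window that sits PAM-proximal of the cut itself.

## Guide selection

`rank_guides()` keeps guides whose cut is within `max_guide_distance`
(default 15 nt) of the edit and sorts by activity first, distance second.
This ordering is deliberate: an efficient guide 14 nt away outperforms a
weak guide 2 nt away, so proximity is only the tie-breaker. Activity
scores are user-supplied (measured or predicted elsewhere); the package
deliberately implements no activity model of its own.

## Donor strand choice

The donor can be synthesised as the targeting strand (T, complementary to
the gRNA) or the non-targeting strand (NT, carrying the protospacer+PAM
sense). The rule table implemented by `choose_strand()`:

| enzyme | edit placement            | strand |
|--------|---------------------------|--------|
| Cas9   | PAM-proximal, beyond 10 nt | T |
| Cas9   | PAM-distal, beyond 10 nt   | NT |
| Cas9   | at/near the cut (≤ 10 nt)  | NT (configurable) |
| D10A pair | between the nicks       | both (top + bottom) |
| Cas12a | any                       | NT |

The distance-dependent rules follow the strand-displacement picture of
SDSA repair: the favoured donor is the one whose 3' sequence can anneal to
the resected overhang. At the cut itself the preference is cell-type
dependent (opposite directions have been observed in different lines), so
the package uses a configurable default (NT) and records the caveat in the
design rationale rather than pretending to a universal rule. The nickase
pair has no canonical T/NT distinction, so both strands are emitted.
`design_cas9()` applies the side-specific rules only beyond the
repair-track trigger distance (10 nt); this is where they were
demonstrated, and it keeps the near-cut default consistent.

## Blocking mutations and the PSSM

If the edit leaves the protospacer and PAM intact, the nuclease re-cuts
the repaired allele and converts precise edits into indels. Donor-encoded
blocking mutations prevent this. Their value depends on position: PAM
positions 2 and 3 are the strongest, and the effect decays PAM-distally
through the spacer; no alternate base is universally preferred.

The package encodes this as a position-specific scoring matrix (PSSM) of
non-negative, base-uniform weights over spacer positions S1–S20 and PAM
positions P1–P3. The **blocking score** of a donor is the sum of weights
of its protospacer/PAM deviations; mutations outside that region do not
block and are excluded (with a warning). The default matrix is calibrated
so that mutating both PAM G nucleotides scores exactly **1.97**, which is
also the decision threshold: scores up to 1.97 are predicted beneficial,
larger scores have an uncertain and possibly detrimental effect (too many
mutations start to suppress HDR). The spacer tiers (0.80 for S17–S20, 0.55
for S13–S16, 0.35 for S9–S12, 0.10 for S1–S8) are package defaults that
reproduce the observed qualitative decay; only the PAM calibration is tied
to the empirically established benchmark. The full matrix round-trips through a TSV
(`read_pssm()` / `write_pssm()`) so an empirically fitted matrix can be
dropped in. Only the threshold classification is implemented; no
score-to-HDR response curve is fitted, because the underlying per-sample
training data is not available.

`select_blocking_mutations()` applies three rules:

1. **Intrinsic disruption.** The edit itself may alter protospacer/PAM
   positions. Substitutions disrupt the positions they change; an indel
   inside the protospacer shifts the register of everything between the
   edit and the PAM, and all those positions count as disrupted. This is
   why a 6-nt insertion at the blunt cut needs no blocking mutation.
2. **Shortcut.** If the intrinsic score reaches 0.985 (one PAM-G
   equivalent), the edit already blocks re-cleavage and nothing is added.
3. **Greedy selection.** Otherwise candidates are taken in descending PSSM
   weight (ties: nearer the PAM first, then alternate base A<C<G<T, with
   the G→C transversion preferred at PAM G positions), restricted to
   synonymous options wherever a coding annotation covers the position.
   Candidates that would push the cumulative score above 1.97 are skipped
   — a lighter candidate may still fit — and selection stops at two added
   mutations (three or four give no further benefit). The objective is
   lexicographic (strongest admissible mutation first); under it, greedy
   selection provably returns the same set as exhaustive search over all
   subsets of size ≤ 2, which the test suite verifies on 100 random
   instances.

When every admissible position in a coding region lacks a synonymous
option, the selection returns an empty set with a machine-readable note —
never a protein-changing mutation.

## Repair-track mutations

For edits more than 10 nt from the cut (the trigger distance; the benefit
was demonstrated at 20–25 nt and the default splits the gap
conservatively), `repair_track_mutations()` places additional mutations
every 5 nt (within the demonstrated 3–7 nt range) along the repair track —
the donor segment between the cut and the edit — exclusive of both
endpoints. In coding sequence each candidate slides up to 2 nt to the
nearest synonymous-capable position and is skipped if none exists;
otherwise a deterministic transversion (A↔C, G↔T) is used. PAM-distal
designs carry track mutations only (a PAM mutation adds nothing there:
the PAM falls outside the conversion zone); PAM-proximal designs combine
a single PAM mutation with the track.

## Donor assembly and validation

`build_donor()` assembles `[5' arm][edited, mutated core][3' arm]` on the
plus strand, then reverse-complements for T/bottom donors, so the two
strands of a design are exact reverse complements. Arms are measured
beyond **both** the cut site(s) and the farthest edit/mutation boundary on
each side — 40 nt by default, floor 30 nt (shorter arms down to the 20-nt
synthesis minimum require an explicit override and are recorded as a
warning). The total length is validated against the 200-nt synthesis cap,
so a 160-nt insertion with 20-nt arms is the largest admissible design;
the error names the excess. The cumulative blocking score of every emitted
design stays within 1.97 by construction.

## Read classification

`amplicon_model()` holds the wild-type amplicon, the HDR allele (wild type
plus the complete donor-encoded allele), and the enzyme's indel window:
8 bp centred on the Cas9 blunt cut (`[cut-4, cut+4)`; symmetric centring
is the package's reading, configurable), or 9 bp starting 3 bp
PAM-proximal of the Cas12a PAM-distal (23-nt) cut and extending
PAM-distal. `classify_reads()` aligns each read globally (affine gaps;
match +2, mismatch −3, gap open 5, gap extend 1 — standard amplicon
defaults, configurable) against both alleles and keeps the higher-scoring
hypothesis, ties going to wild type.

Calls follow the window logic: **NHEJ** is a wild-type read with an indel
intersecting the window; **perfect HDR** is an HDR read with no mismatch
or indel across the window and the donor-mutation positions; **imperfect
HDR** is an HDR read with an additional window indel; everything else is
**WT** — substitution-only noise away from donor positions never flips a
call. Reads under 50% identity to both alleles are reported separately as
unassigned and excluded from denominators.

Two numerical details matter. First, equal-score indel placements are
resolved toward the predicted cut by score-preserving rotations within the
indel's repeat context (the shift stops when the indel reaches the cut or
its context breaks). Second, an HDR call requires the donor-encoded
replacement to actually be present in the read: a mismatch inside the
replacement, or an indel that cannot be rotated out of it, refutes the
HDR hypothesis and the read is re-classified under the wild-type
alignment. Without this rule an NHEJ insertion of about the replacement's
length at the cut aligns "better" to the HDR allele and inflates
imperfect-HDR counts. This also resolves what "perfect" tolerates: only
the window and donor positions are constrained; substitutions elsewhere in
the amplicon are treated as sequencing noise.

`digest_fraction()` implements the restriction-digest quantification used
with EcoRI reporter insertions: mean molar concentration of the two cut
products over (that mean plus the uncut product), times 100.

## The simulator

`make_toy_locus()` generates a random locus with planted features — Cas9
PAMs on either strand, Cas12a TTTV PAMs, a PAM-out (or PAM-in) nickase
pair with chosen spacing, a CDS with chosen frame — and scrubs a 30-nt
guard band around each feature (a wide corridor around a planted pair) of
accidental PAM motifs, so guide discovery inside the band recovers exactly
the planted truth. `simulate_reads()` draws multinomial outcome counts and
emits WT copies, NHEJ copies with a window-intersecting indel (geometric
size, mean 3, insertion/deletion 50:50 — a synthetic stand-in, not an
empirical NHEJ spectrum), perfect-HDR copies, and imperfect-HDR copies
with an extra window indel, under uniform substitution noise (0.5% per
base by default). Everything is reproducible bit-for-bit from one integer
seed through R's RNG.

Two identifiability constraints keep the simulated truth meaningful: the
extra indel on an imperfect-HDR read never damages the donor-encoded
replacement (the definition of imperfect HDR is "edit present plus
additional indels"), and an NHEJ draw whose junction happens to spell out
an extra copy of the replacement is rejected — such a read genuinely
carries the intended allele and no classifier could, or should, separate
it. Under these conditions the classifier's confusion matrix on
error-free reads is exactly diagonal, which the tests assert.

What the simulator does **not** emulate: realistic NHEJ indel spectra,
microhomology-mediated junctions, sequencing quality profiles, chimeric
reads, or large structural outcomes. Passing tests therefore demonstrate
the correctness of the geometry, scoring, selection and classification
logic under the stated model — not classifier performance on real MiSeq
data, where alignment and filtering choices dominate.

## Problem sizes used by the test suite

The property suites run at sizes chosen to exercise the invariants
thoroughly while keeping a full check quick on a laptop: the guide finder
is compared with a brute-force scan on 100 random 1-kb loci; greedy
blocking-mutation selection is compared with exhaustive subset search on
100 instances; the coding invariant (auxiliary mutations never change the
protein) runs on 1,000 random coding loci across frames and strands; and
outcome-fraction recovery uses 2,000 reads per seed across 20 seeds at a
0.5% substitution rate, with agreement required within three binomial
standard errors.

## Known limitations

* Activity prediction, off-target scoring, and genome-scale scanning are
  out of scope; loci are single FASTA records.
* The Cas12a blocking rules are rule-based (PAM TTTV→TVTV or a synonymous
  protospacer option near position 14); no Cas12a PSSM is provided.
* The spacer-tier PSSM magnitudes are qualitative defaults, not fitted
  values; users with calibration data should supply their own matrix.
* The H840A nickase (51–68 nt window) is not a supported design path; the
  D10A enzyme is the recommended and implemented one.
* Strand preference for Cas12a PAM-proximal placements has not been
  systematically measured; the NT strand is applied universally.
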