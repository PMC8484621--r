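Package: ssodn
Title: CRISPR HDR Donor Template Design and Amplicon Editing Quantification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design of single-stranded oligodeoxynucleotide (ssODN) donor
    templates for homology-directed repair (HDR) with S. pyogenes Cas9,
    paired Cas9 D10A nickases, and A. s. Cas12a. Implements empirically
    derived design rules: guide ranking in which activity dominates
    proximity, donor strand choice from the position of the edit relative
    to the cut site, blocking mutations scored by a position-specific
    scoring matrix and capped at the two-PAM-G benchmark score of 1.97,
    codon-preserving (silent) mutation selection, paired-nickase geometry
    (PAM-out, 40-68 nt nick spacing), and Cas12a placement rules (spacer
    positions 12-16). Also provides an amplicon read classifier that
    quantifies WT, NHEJ, perfect-HDR, and imperfect-HDR outcomes using
    enzyme-specific indel windows, a restriction-digest HDR fraction
    calculator, and a deterministic simulator of toy loci and read sets
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
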