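Package: binderforge
Title: Desk-Scale Miniprotein Binder Design and Screening Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for de novo miniprotein binder design on the
    ferredoxin (beta-alpha-beta-beta-alpha-beta) fold, together with the
    analytics used to screen and characterize the resulting binders.  Covers
    ABEGO-guided blueprint enumeration and ranking from topology occurrence
    statistics, staged torsion-space backbone assembly with clash, strand
    pairing, compactness and cavity filtering, RGD-motif grafting by rigid
    Kabsch superposition, geometric interface scoring (Shrake-Rupley solvent
    accessible surface area, buried area, class-weighted contact energy),
    sort-seq dissociation-constant estimation from FACS count tables,
    site-saturation-mutagenesis entropy profiles and specificity calls,
    combination-library enumeration, and global binding-model fits (1:1
    biosensor kinetics, three-parameter dose-response, shared-plateau
    competition with EC50 to KD conversion).  All inputs can be regenerated
    from seeded synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
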