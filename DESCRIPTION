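Package: kaspop
Title: KASP Genotype Calling and Temporal Analysis of an Adaptive
    Introgression Island
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to monitor adaptive introgression with ancestry-informative
    KASP assays. Converts two-channel allele-specific fluorescence into
    variant allele fluorescent fractions (VAFF), calibrates per-run cutoffs
    from positive controls, calls allele dosages and classifies individuals
    to species with a multiplex hybrid index. Computes allele frequencies
    per population and sampling period, exact tests of temporal change
    (complete-enumeration Fisher and Freeman-Halton tests, exact Wilcoxon
    signed-rank and sign tests, Benjamini-Hochberg adjustment), and pairwise
    linkage disequilibrium r2 from unphased genotypes by EM estimation of
    two-locus haplotype frequencies. Includes a forward-in-time Wright-Fisher
    simulator of an introgression island (beneficial core allele at
    migration-selection balance, deleterious hitchhikers in the shoulders,
    recombination along a marker map) that emits pipeline-ready fluorescence
    tables with truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
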