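Package: pedcascade
Title: Pedigree-Constrained Rare-Variant Prioritization and Promoter Motif Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying causal non-coding variants in
    fully penetrant autosomal-dominant disease from family sequencing data.
    Refines a disease locus by haplotype sharing among affected pedigree
    members (obligate-recombinant mapping), runs a configurable filter cascade
    over multi-sample variant calls (locus restriction, reference-panel allele
    frequency, heterozygous-sharing and unaffected-exclusion genotype
    patterns, phasing against a married-in parent, consequence classes),
    classifies survivors against transcript models, converts HGVS c.-N
    promoter coordinates on either strand, and scans wild-type versus mutant
    promoter sequences with position weight matrices to call gained and lost
    transcription-factor binding sites. Includes simulators for pedigrees,
    cohort variant sets, marker genotypes with planted recombination
    breakpoints, and dual-luciferase reporter measurements, plus RPKM and
    one-way ANOVA helpers for downstream assays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
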