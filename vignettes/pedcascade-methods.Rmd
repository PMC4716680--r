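---
title: "Methods: pedigree-constrained variant prioritization and promoter motif analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-constrained variant prioritization and promoter motif analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcascade)
```

## The disease model and its assumptions

Everything in this package assumes a **fully penetrant autosomal-dominant**
disease: carrier status and affection status are the same set, every
affected individual is heterozygous for one founder allele, and that
allele travels on a single ancestral haplotype. Three consequences drive
the design:

1. all affected members of a family share the disease haplotype around the
   causal position, so markers at which an affected provably lacks the
   shared allele are *obligate recombinants* that bound the locus;
2. a variant present in an unaffected relative, or exceeding a population
   frequency compatible with the disease prevalence, cannot be causal;
3. a *married-in* unaffected parent (no recorded parents, co-parent of a
   child inside the pedigree) carries no disease haplotype, so any variant
   they carry phases onto their child's unaffected haplotype.

Incomplete penetrance, phenocopies and de novo events are outside the
model; with them, the exclusion filters below would no longer be sound.

## Locus refinement

`infer_disease_haplotype()` assigns, per marker, the allele compatible
with carriage by all genotyped affecteds. Markers fall into three states:
**shared** (exactly one such allele), **recombinant** (none — obligate
crossover evidence), and **uninformative** (several candidates survive,
e.g. when all affecteds are identically heterozygous). Where an affected's
parents are typed, candidates the transmitting (affected) parent does not
carry are eliminated; this is the only use of pedigree structure here, and
over-pruning falls back to "uninformative" rather than guessing.
Uninformative markers contribute **no** breakpoint evidence: they neither
extend nor break a shared run. This is deliberately conservative — imputing
phase at an ambiguous microsatellite could fabricate or hide a breakpoint.

`refine_interval()` reports the maximal recombination-free run of markers,
**closed at the outermost shared markers** of that run. The boundary
convention was genuinely open (an interval could equally be reported as
open at the flanking recombinant markers); we pin the closed-at-shared
convention because mapping studies quote their boundary marker coordinates
as interval ends, and the packaged marker fixture is built so this
convention reproduces the published interval chr20:17,641,482–18,949,130
(1.3 Mb) exactly. A corollary worth noting: a single shared marker flanked
by recombinant markers refines to the degenerate closed interval at that
marker's own position, not to the open interval between the flanks.
Ties between equally supported runs go to the run with more shared
markers, then the wider one, then the leftmost — determinism over
cleverness. SNPs and microsatellites are treated identically as
multi-allelic markers; genotypes are unordered pairs (`a/b`).

The test suite checks this algorithm against a brute-force oracle that
enumerates every contiguous marker range compatible with the genotypes
(200 random panels of ≤ 8 markers × ≤ 6 affecteds), and checks
monotonicity: adding an affected individual can only shrink the interval.

## The filter cascade

`run_cascade()` applies independent predicates in the order
locus → frequency → genotype pattern → phase → consequence. Because each
filter is a pure per-variant predicate, the survivor *set* is provably
order-invariant (tested by permutation); the order only shapes the
per-stage counters. Every variant gets a complete `FilterTrace`, and
survivors + failures always partition the input.

Tunables, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `maf_threshold` | 0.005 | fail if AC/AN exceeds this in a filter panel |
| `maf_panels` | 1000G, ExAC | panels the threshold applies to |
| `annotation_panels` | UK10K, GoNL, UCL | reported, never filtered on |
| `deep_intronic_distance` | 100 bp | "deep" is *strictly* more than this |
| `consequence_keep` | missense | classes kept in exonic mode |

The panel split deserves explanation. The published candidate tables that
the fixtures encode contain survivors whose frequency in UK10K (60/7,562 ≈
0.79%) or GoNL (7/998 ≈ 0.70%) exceeds 0.5%; a literal "any panel" rule
would have removed them. Whether the original screen applied the threshold
per panel or to a union is not stated; we resolve the ambiguity by
filtering on the two largest, ancestrally broadest panels and carrying the
rest as annotation, which reproduces both printed tables and remains fully
configurable. Two further conventions: a missing call in an excluded
(control) sample passes with a warning rather than silently discarding a
candidate on a no-call, and "het in all required samples" is strict — a
homozygous-alternate affected fails, as it should under a dominant model.

Annotation precedence is promoter > coding > intronic >
non-coding-transcript exon > intergenic, with missense/synonymous decided
by mutating the codon in the transcript's spliced CDS (gene strand) and
comparing translations. One supplied isoform per gene; no isoform
collapsing.

## Promoter coordinates and the motif differential scan

HGVS c.−N offsets have no position 0 and, in this package, no intron
adjustments: the modelled region is uninterrupted sequence upstream of the
translation start (+1 = the A of ATG). On a minus-strand gene
g = translation_start + |c.−N|, and alleles are complemented between gene
strand and genome plus strand. UTR-crossing c. arithmetic is explicitly
out of scope — all modelled variants sit within 370 bp of the ATG.
Duplications insert the copy immediately 3′ of the duplicated span on the
gene strand (HGVS dup semantics). `apply_variant()` refuses to mutate when
the stated reference base does not match the sequence.

`scan_pwm()` scores every window on both strands with
log-odds = Σ log₂(p_base/background) against a uniform background, calling
a hit at ≥ `threshold` × maximal score. The default threshold is **0.80**:
the thresholds of the commercial tools used in the original in-silico
analysis are unpublished, so the packaged PWMs are *toy* matrices —
near-point-mass 8-mers built so that one mismatch falls well below 0.8 —
and the reproduction target is the qualitative gain/loss pattern, never
matrix-exact scores. `diff_scan()` restricts comparison to hits
overlapping the mutated span widened by one motif length, mapping mutant
coordinates back through the insertion offset, and calls a TF *gained*
iff the mutant and not the wild type has such a hit (symmetrically
*lost*). The scanner is cross-checked in the tests against an independent
window scorer and against `Biostrings::matchPWM`.

`conservation_profile()` reports per-column identity to a reference row of
a supplied alignment (alignment construction itself is out of scope), and
`conserved_window()` finds the widest window at a mean-identity cutoff
(default 0.8) containing the mutated positions.

## Assay statistics

RPKM is count·10⁹/(length_bp · library size); the expression presence
cutoff is RPKM ≥ 1.0 (the source data report presence/absence only; the
observed values straddle 1 naturally, and the cutoff is configurable).
Dual-luciferase normalization divides firefly by Renilla per well,
averages technical triplicates within each biological replicate, and
scales by the wild-type mean so wild type ≡ 1. The **biological
replicate** (independent experiment) is the replication unit: the one-way
ANOVA runs on per-replicate means, not on the 3× pseudo-replicated wells.
The ANOVA is the classical equal-variance fixed-effects F test, with the
degenerate zero-between-variance case pinned to F = 0, p = 1.

## What the generators emulate — and what they do not

`simulate_pedigree()` gene-drops one founder allele through a family in
which every affected marries an unrelated spouse and has a fixed sibship
(default 3; penetrance fixed at 1.0 by the disease model). Unaffected
offspring do not reproduce in the simulation — matching how disease
pedigrees are ascertained and drawn, not how families grow.
`simulate_cohort_variants()` draws background variants uniformly in the
locus with a 70%/30% rare/common frequency mixture across five reference
panels (totals mirroring 1000G/UK10K/GoNL/ExAC plus a small in-house
panel), each panel independently absent with probability 0.4 to exercise
the "not identified" pathway. Marker genotypes are unphased; breakpoints
are planted per individual. Reporter simulations use multiplicative
log-normal noise (default CV 5%) around known effect sizes, so parameter
recovery has an exact truth. The fixture effect sizes (wild type 1;
mutants 2.5, 2.0, 1.8, 1.6) encode only the qualitative published outcome
— every mutant promoter more active than wild type — because the source
figure prints no numbers; mutant fold-changes are therefore validated by
parameter recovery on simulation only.

None of the generators model sequencing error, genotyping failure,
population structure, linkage disequilibrium between background variants,
or mosaicism. Passing tests show the *inference chain* is correct under
its stated model, not that the pipeline is robust to real-data artifacts.

## Fixtures and problem sizes

The packaged case-study bundle encodes the published candidate tables (19
and 18 rows, with per-panel allele counts transcribed verbatim), plus ≥ 20
decoys per cohort each violating exactly one filter — audited in the tests
via the filter traces. The wild-type promoter is a **synthetic** 1,824 bp
sequence (shipping the reference genome would make the package
download-free no longer): its obligations are its length, the wild-type
bases at the four mutated positions, the published 22 bp duplicated
sequence (given on the genome plus strand), and single designed
occurrences of the two packaged binding sites. The published duplication
label (`c.-339_361dup`) spans 23 c-positions while its genomic annotation
spans 22 bp; the fixture follows the genomic span and carries the label
verbatim without validating it. The marker fixture spans 2.7 Mb with
eight genotyped affecteds and two planted obligate recombinants. Property
checks run at deliberately desk-scale sizes — 100 seeded cohort
simulations (30 background variants each), 200 random marker panels
against the brute-force oracle, 200 reporter/ANOVA simulations — chosen so
the whole suite completes in about a minute on one core while still
exercising every code path.

## Known limitations

- Single isoform per gene; no splice-region or UTR consequence classes
  beyond the distance-based intronic split.
- The phase filter trusts the married-in flag derived from pedigree
  topology; a genotyping error in that parent silently removes a true
  candidate (mitigated by the warning-on-missing contract).
- PWM scanning assumes independent positions and a uniform background;
  the packaged matrices are qualitative stand-ins, not measured motifs.
- Phased (`|`) VCF genotypes are treated as unphased; BCF, tabix and
  liftover are unsupported; coordinates are build-opaque (the fixtures
  label theirs hg38).
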