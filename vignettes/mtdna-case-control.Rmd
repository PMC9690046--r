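---
title: "Calling mitochondrial control-region variants and testing case-control association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mitochondrial control-region variants and testing case-control association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovar)
```

## The problem this package addresses

Case-control studies of mitochondrial DNA typically start from consensus
sequences — complete mitogenomes of ~16,569 nt or short hypervariable-region
(HVR) amplicons — deposited with nothing but a FASTA record and a group
label. Turning those into association statistics requires a chain of small
but error-prone steps: aligning each sequence against the rCRS coordinate
system, naming each difference canonically (deceptively hard inside
homopolymers), classifying the hypermutable D310 poly-C tract, discarding
systematic sequencing artifacts ("phantom polymorphisms"), and building
carrier-frequency 2x2 tables whose denominators respect the fact that a
sample only counts where its sequence actually covers the position.
`mitovar` implements that chain end to end, together with a synthetic-cohort
generator that implants a known truth so every stage can be validated
without downloading a single external sequence.

## The reference and its coordinate system

All coordinates are 1-based rCRS positions and the molecule is circular; the
control region (16024..576) wraps the origin and is represented explicitly
as a wrapping interval rather than two rows, so the region list matches the
field's usual tables one-to-one. The packaged reference
(`inst/extdata/rcrs_synthetic.fasta`, built by `synthetic_rcrs()`) is a
*synthetic stand-in*, not the NC_012920 sequence: a deterministic
pseudo-random background with every locus this package's analyses touch
pinned to its rCRS allele — most importantly the D310 context (C7 at
303-309, T at 310, C5 at 311-315) plus the reference alleles at the
control-region, MT-ND3, rRNA and MDP positions that appear throughout the
documentation and tests. Labels, windows and statistics behave exactly as
against the real reference, and users holding the genuine NC_012920 FASTA
can pass it to `load_reference()` unchanged. The background deliberately
uses the high bits of its internal linear congruential generator; the low
bits of a power-of-two-modulus LCG are periodic, which would make the
background self-similar and alignments ambiguous.

Two of the published MDP windows required a decision. The source table lists
SHLP1 with the same coordinates as MT-ND3 (an apparent misprint) and one
section gives SHLP5 the same window as SHLP1; the defaults therefore use
SHLP1 = 2485..2559 and SHLP5 = 2780..2854, and both are overridable through
`region_table(overrides = ...)`. Similarly, m.16519T>C is annotated by
coordinates (control region, *outside* HVR1's 16024..16383) even though
published tables sometimes file it under the HVR1 block.

## Alignment

Near-complete genomes (>= 15,400 nt, the conventional completeness cutoff)
are aligned globally with an affine-gap banded dynamic program (default
band half-width 200, retried once with a doubled band if the optimal path
touches the band edge); shorter fragments are aligned semi-globally with
free reference end gaps, which locates an HVR amplicon at its window
without penalty. Default scores are match +1, mismatch -2, gap open -4,
gap extend -1 — deliberately mild on substitutions relative to gap pairs so
that, at the D310 tract, a single substitution is preferred over a
deletion+insertion pair and a substitution adjacent to an indel merges into
one delins event (fewest-variants parsimony). IUPAC ambiguity codes score
as a match against any component base, so a heteroplasmic site does not
drag identity down or seed spurious indels. Sequences below 90% identity
are rejected as unalignable rather than force-called. Samples are assumed
linearized at the rCRS origin, as deposited mitogenomes are; origin-spanning
inputs fail with a clear error.

## Variant normalization

Raw differences are trimmed to a minimal span and indels are shifted to
their 3'-most equivalent placement (HGVS convention). This single rule
reproduces the field's names for the poly-C events: a C inserted *anywhere*
in the 311..315 run emits `m.315dup`, one in 303..309 emits `m.309dup`, a C
lost from the first run emits `m.309del`, and the three-base replacement at
310 emits `m.310delinsCCTC`. The published mention of "left-shifted" and
"right-shifted" forms of m.309del is resolved by always emitting the 3'
representation. Insertions equal to the immediately preceding reference run
are folded into duplications. The VCF writer performs the opposite
conversion — 5'-shifting plus left-padding base — explicitly, and the tests
re-apply both representations to the reference to prove they describe the
same molecule.

## D310 typing

The locus window is fixed at 302..318 (one base of context beyond the
repeat on each side, because 3'-shifting can push anchors to the run ends).
Classification is deliberately variant-set-driven: no variants in the
window is `reference`; exactly one variant matching a named allele gives
that category; anything else — multi-variant tracts, or a heteroplasmic
base inside the window, for which tract length is undefined — is the
explicit category `other` rather than an error, because the tract is
genuinely highly polymorphic. Note a structural identity worth knowing:
applying m.310del and m.315dup to the same molecule yields a tract
string-identical to m.310T>C, which is why those two alleles can never be
called together — the parsimony rule collapses the pair to the single
substitution. Tract lengths are measured from the literal aligned sample
bases over 302..316, not inferred from labels.

## Phantom screening

The screening rule takes a reference "frequency score" per variant (its
occurrence count in a panel of mitogenomes; the published procedure used a
2,196-genome panel, which is not redistributable, so the panel is an input
table here) and combines it with within-cohort recurrence: score >=
threshold (default 3) is common; score < threshold but shared by >=
`min_shared` samples (default 2) is retained and flagged *rare*; score <
threshold and fewer carriers is a *phantom candidate*, excluded from
association under the default policy (a report-only policy exists). The
six-variant backbone (m.263A>G, m.750A>G, m.1438A>G, m.4769A>G, m.8860A>G,
m.15326A>G) is whitelisted by default, mirroring how haplogroup-defining
polymorphisms are retained in practice. Two panel defaults ship: the cohort
self-panel (used loudly when no panel is given) and `truth_panel()`, which
derives a panel from a simulation truth table so tests have a panel with
known properties.

## Carrier tables and the association test

Denominators are coverage-derived: a sample enters a variant's 2x2 table
only if its footprint covers the variant's full span, which is what makes
tables built from mixtures of complete genomes and HVR fragments honest.
The test is the uncorrected Pearson chi-square with 1 df and upper-tail p.
The choice of *uncorrected* is empirical: regenerating a published
breast-cancer association table from its printed carrier counts reproduces
all twelve internally consistent printed p-values to within +-0.002 without
continuity correction, and none of the borderline ones with Yates'
correction (the packaged `carrier_counts.tsv` and
`tests/testthat/test-acceptance.R` carry that check; two further printed
p-values are inconsistent with their own printed counts and are documented
as irreproducible). Significance is flagged at alpha = 0.05 with no
multiple-testing correction, matching the published analysis; a
Bonferroni-adjusted alpha is trivial for a user to apply to the returned
p-values.

## The synthetic cohort generator

`simulate_cohort()` draws each sample independently: spec'd variants as
Bernoulli implants per group, exactly one D310 allele from a categorical
mix (the remainder of the mass being the reference tract, so m.310del and
m.315dup are mutually exclusive by construction), optional Poisson private
singletons, at most one IUPAC heteroplasmic site per sequence, systematic
phantom artifacts implanted as the same alternate allele at the same
position in a fixed number of samples across both groups, and a stated
fraction of samples emitted as HVR1 or HVR2 fragments (1/3 vs 2/3 by
default, the split seen among deposited partial sequences). Conflicting
implants are skipped and logged with priority D310 > spec'd variants >
artifacts; singletons and heteroplasmy are re-drawn to free positions.
Identical specs (including the seed) produce byte-identical FASTA and truth
tables.

`study_mirror_spec()` encodes the study conditions this package was
validated against: 78 cases vs 34 controls, carrier probabilities equal to
the published carrier fractions, heteroplasmy rate 0.2 (about one in five
published complete sequences carried a heteroplasmic site), seven
single-carrier artifacts, a quarter of samples as fragments, and no private
singletons. One wrinkle is documented rather than hidden: the published
D310 carrier fractions sum to slightly more than 1 within each group
(79/78 in cases, 35/34 in controls) because the printed denominators are
inconsistent with each other, so the categorical mix is normalized
proportionally — m.315dup in cases becomes 47/79 = 0.595 rather than
0.602.

What the generator does *not* emulate: phylogenetic haplotype structure
beyond the six-variant backbone, mutation-rate heterogeneity along the
molecule, NUMT contamination, and read-level errors (inputs are consensus
sequences). Passing tests therefore demonstrate the correctness of the
pipeline's logic on clean consensus data, not robustness to upstream
assembly artifacts.

## Numerical and scale choices

Problem sizes in the shipped tests were chosen to exercise every path while
keeping a full run comfortable on a laptop: the truth-recovery check calls
all 112 mirror samples through banded alignment (~90 s), the D310 oracle
enumerates all 64 tract strings `C^a {T|C|eps|CCTC} C^b` (a in 6..9, b in
4..7) through HVR2 fragments, chi-square calibration uses 1,000 random
tables against the closed-form `p = 2*Phi(-sqrt(X^2))` identity plus 500
null cohorts of 30+30 samples, and the frequency-calibration check averages
200 independently seeded mirror cohorts. `scripts/acceptance.R` re-runs the
same computations from scratch against the installed package.

## Known limitations

* Alignment assumes origin-linearized input; a mitogenome deposited with a
  rotated origin must be rotated by the user first.
* Heteroplasmy handling is consensus-level (one IUPAC site per sequence in
  simulation; any number on calling); no allele-fraction model.
* `population_diffs()` compares profile matrices over the common callable
  interval; inserted bases are invisible to it (deletions count as an
  allele), so it is a substitution-oriented summary, as its classical
  definition intends.
* The phantom rule with a cohort self-panel cannot distinguish a genuine
  private variant from an artifact seen once; that is a property of the
  published rule itself, which is why the panel is an explicit input.
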