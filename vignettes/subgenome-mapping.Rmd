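---
title: "Discriminating subgenome-specific loci in an allo-octoploid S1 population"
author: "subgenomap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating subgenome-specific loci in an allo-octoploid S1 population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgenomap)
```

## The inheritance model and its assumptions

An allo-octoploid genome consists of four diploid subgenomes; at meiosis
each subgenome forms bivalents strictly within itself, so every gamete
receives exactly one homolog per subgenome and homoeologous chromosomes
never exchange material. `subgenomap` encodes a locus by the alleles on the
8 parental homologs as a string over `{A, B, O}` (`O` = null: the marker
target is absent from that homolog), grouped into 4 subgenome pairs, e.g.
`ABBBOOOO`.

Three assumptions shape everything downstream:

1. **Disomic inheritance.** Each subgenome transmits one of its two alleles
   with probability 1/2, independently across subgenomes.
   `gamete_distribution()` enumerates the $2^4$ homolog choices exactly.
2. **Dosage-blind calls.** Genotyping arrays report three clusters only, so
   an offspring with at least one A and one B anywhere across its 8
   homologs is called `AB`; all-A is `AA`, all-B is `BB`. `AAAB` and `AB`
   are indistinguishable.
3. **Presence is per subgenome.** A valid configuration has each subgenome
   pair either fully null (`OO`) or fully present. A consequence worth
   spelling out: under this invariant the "null phenotype" (an offspring
   with no allele at all) has probability exactly 0, because any present
   subgenome contributes an allele to every gamete. Heterozygous-null pairs
   such as `AO`, which would make null offspring possible, are excluded by
   the model's domain — a deliberate simplification matching the diallel
   setting.

With these rules, selfing a subgenome-specific heterozygous locus
(`ABOOOOOO`) gives AA:AB:BB = 1:2:1, while homoeologous configurations
(`ABBBOOOO`, `ABBBBBOO`, `ABBBBBBB`) give 0:3:1 — the fixed B background of
the extra subgenomes masks the AA class. This is the entire basis for
discriminating candidate subgenome-specific loci from segregation data, and
why an S1 population is used: in an F1, specific and non-specific loci can
both segregate 1:1.

```{r ratios}
expected_segregation("ABOOOOOO")
expected_segregation("ABBBBBOO")
expected_segregation("AAOOOOOO", "ABOOOOOO")   # F1: 1:1 either way
```

## What the simulator emulates — and what it does not

`make_genome()` + `simulate_population()` produce the *stated world* the
pipeline is validated against: 7 homoeologous groups of 4 chromosomes
(the octoploid strawberry layout), per-HG genetic lengths set to the mean
linkage-group lengths reported for that crop (78.8–111.5 cM), 36 loci per
chromosome (~1000 total), 78% subgenome-specific configurations (the
codominant share among mapped loci in the motivating dataset), 164 S1
individuals, Poisson crossovers with no interference (the Haldane model,
chosen for self-consistency with the mapping function used downstream),
uniform-wrong-call genotyping error and uniform missingness.

Two defaults are stand-ins, not measurements: `error_rate = 0.005` and
`missing_rate = 0.02`. Array error rates for this platform are not
published (the motivating study notes calling errors could not all be
corrected); small-but-nonzero values were chosen once and are exposed in
the configuration.

Sampling uses the interval-parity identity of the Poisson process (the
homolog source flips between consecutive loci with the parity of a
Poisson(d/100) count), which is exactly equivalent to drawing crossover
counts and uniform breakpoints — the test suite checks the two
implementations against each other and against Haldane's closed form.

Not modelled: read-level or intensity-level data, off-target-variant
clusters, crossover interference, polysomic or segmental inheritance,
homoeologous exchange, multi-allelic SSR alleles (recode to a
reference/alternate diallel before entry). Homoeologous copies outside a
locus's host chromosome are always homozygous `B`, so they contribute a
constant background and need no meiotic simulation; truly heterozygous
duplicate regions (e.g. an `ABABABAB` genotype) are therefore outside the
simulator's world. A green test establishes that the pipeline recovers the
parameters of *this* world; real arrays add cluster-calling artefacts,
segregation distortion from selection, and marker-density heterogeneity
that it does not represent.

## Classification

`classify_locus()` fits the observed (AA, AB, BB) counts against the
candidate classes — 1:2:1, 0:3:1 in both orientations, 1:1, monomorphic —
and keeps the compatible class with the largest χ² goodness-of-fit p-value
(degrees of freedom: nonzero expected classes − 1).

Numerical choices that matter:

- **Off-class tolerance** (`offclass_tol = 0.03`). A strict reading of the
  zero-expectation rule (any observed call in a zero-probability class ⇒
  χ² = ∞) makes dominant classification collapse under realistic error: at
  a 1% error rate more than half of true 3:1 loci show at least one stray
  `AA` call in 164 individuals. Calls in zero-expectation cells are
  therefore excluded as presumed miscalls up to 3% of scored calls; beyond
  that the class is incompatible. The primitive `chi2_goodness_of_fit()`
  keeps the strict rule.
- **Filters.** The motivating workflow's published filter ("X² ≥ 50")
  selects *worse*-fitting loci if taken literally, so retention is
  implemented as a goodness-of-fit floor, `p ≥ min_p` (default 0.01),
  plus the missing-data cap (≤ 20 calls). Both are configurable, so the
  literal threshold can be reproduced if desired.
- **Distortion** is flagged at best-class `p < 0.05` (configurable); no
  published threshold exists for the reported distortion percentages.

## Linkage mapping

An S1 is an F2 design for linkage. `estimate_r()` runs EM over the 16
latent gamete-pair combinations per individual, which uniformly handles
codominant and dominant loci and both phases; the better phase's
likelihood wins. The estimate is clamped to [0, 0.5], and when the
likelihood at the optimum does not exceed the independence likelihood by
more than 1e-7 the pair is reported at exactly r = 0.5 with LOD 0 (the
likelihood is flat there for degenerate tables and EM would otherwise
stall arbitrarily close to the boundary). A property test checks EM
against an exhaustive grid-search ML oracle at 1e-4 resolution on hundreds
of random tables.

Design choices in the pipeline, with rationale:

- **Grouping threshold.** `group_loci()` defaults to the workflow's
  confirmation parameters (LOD 2.0, r ≤ 0.4). But de novo single-linkage
  grouping is a multiple-testing problem: measured on independent loci,
  about 0.2% of pairs reach LOD 2 by chance (with r̂ ≈ 0.37, inside the
  r ≤ 0.4 gate), which at ~7000 pairs per homoeologous-group partition
  yields ~15 chance edges and chains homoeologous chromosomes together.
  The original workflow never did de novo LOD-2 grouping — LOD 2.0 only
  confirmed groups pre-formed by graphical genotyping. `build_map()`
  therefore uses `grouping_lod = 5` (zero chance edges in 7140 simulated
  independent pairs; truly adjacent loci carry LOD ≫ 10, so no true edge
  is lost).
- **Ordering.** Greedy insertion minimising the sum of adjacent
  recombination fractions, polished by window-3 ripple passes and 2-opt
  segment reversals until stable. The 2-opt moves repair reversed blocks
  that a width-3 window cannot reach (observed on ~1 LG in 28 without
  them). Ties break by locus id; orientation follows ascending anchor
  positions, else the smaller terminal locus id — everything is
  deterministic.
- **Binning before ordering.** Loci with zero observed recombinants on
  jointly scored individuals share a bin (representative: smallest locus
  id) and a single position.
- **Distances from observed calls.** Solitary-missing imputation (fill a
  missing call only when both nearest flanking calls agree) is applied to
  the output graphical genotypes but *not* before distance estimation: the
  EM is already full-information ML under missing data, and the flanking
  rule silently erases genuine double crossovers — measured at a ~4%
  downward bias on adjacent r̂ at 2% missingness, enough to push LG
  lengths outside the ±15% recovery band. Imputation remains useful for
  inspection and is idempotent by construction.
- **Dominant loci.** Dominant × dominant pairs in repulsion carry almost
  no linkage information in an F2 design and can be excluded from grouping
  edges. The pipeline instead maps codominant loci structurally and
  attaches dominant loci at the cM position of the mapped bin with the
  nearest orthologous reference position (ties to the smaller physical
  position). Note the deliberate limitation: with four homoeologs
  anchoring to the same reference chromosome, orthology alone cannot
  decide *which* subgenome's LG a dominant locus belongs to — positions
  are recovered well (≥90% within 5 cM in the simulated world), LG
  identity is not guaranteed. Attached loci are excluded from LG length
  endpoints.

Map distances use Haldane's function $d = -50\ln(1-2r)$ (no interference),
with fractions at or above 0.4999 rejected or capped per the `cap` flag.

## Comparison against a reference

`collinearity_stats()` reports per LG (≥3 anchored loci) the majority
reference chromosome, the signed Spearman ρ of cM versus bp, and inversion
segments — maximal runs of ≥3 loci with strictly decreasing physical
position after orientation normalisation. `coverage_ratio()` needs a
definition the motivating work never states; the one chosen (and
documented prominently because summary tables depend on it) is the
anchored physical span divided by chromosome length, clamped to [0, 100] —
monotone non-decreasing in the anchor set. `tally_haplosnps()` counts the
four ancestor-match categories (Y-N, Y-Y, N-Y, N-N) per LG and labels each
HG's highest-Y-N LG "A" (ties: all reported; fragmented "A" candidates
with non-overlapping spans should be joined explicitly, never silently —
a 10 cM artificial gap is the convention). `depth_comparison()` applies
the classical equal-variance two-sample t-test between PHR-like and
NMH-like probe depths and histograms depth normalised by each class's
mode; in the simulator, homoeologous probes draw Poisson(kλ) reads with k
the number of present subgenomes, so their depth distribution is
multi-modal while specific probes are single-peaked. This separation is
idealised — real depth ratios overlap far more than Poisson mixtures do.

## Degenerate inputs and edge behaviour

All-missing loci are flagged, never errors; pairs with <2 jointly scored
individuals are undefined and excluded from grouping; single-locus groups
map at position 0; an LG with <3 anchors has undefined collinearity; a
class with <2 depth records makes the depth comparison undefined;
`haldane_cm(0.5)` is a domain error unless capping is requested. Every
stochastic step takes an explicit seed and simulation output is
bit-for-bit reproducible given (genome, configuration, seed).

## Known limitations

- The per-locus classifier assumes the candidate ratio set of the S1/F1
  diallel model; exotic ratios (e.g. from an `ABABABAB` region) fall to
  the nearest candidate or "other".
- Two-point ordering only; no multipoint likelihood, no QTL analysis, no
  consensus maps across populations.
- The nearest-orthology attachment of dominant loci cannot resolve
  subgenome identity (see above).
- The goodness-of-fit-jump locus-removal step of commercial ordering
  software has no published closed form; the SARF-based polishing here is
  a functional replacement, not an equivalent.
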