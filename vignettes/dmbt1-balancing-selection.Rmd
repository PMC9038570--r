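---
title: "Dissecting balancing selection at DMBT1: methods and design"
author: "dmbtsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting balancing selection at DMBT1: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmbtsel)
```

## The scientific problem

The human *DMBT1* gene encodes a salivary pattern-recognition
glycoprotein (gp340 / salivary agglutinin) whose bacteria-binding region
is a tandem array of scavenger receptor cysteine-rich (SRCR) domains.
The array is highly copy-number variable: individual alleles carry
between 7 and 21 SRCR repeat units. The 5' end of the gene carries one
of the strongest balancing-selection footprints in the human genome —
two deeply diverged SNP haplotypes segregating at intermediate
frequency, which inflate intermediate-frequency variation and hence
Tajima's D. The analytical question this package addresses is whether
that footprint is carried by linkage of each SNP haplotype clade to a
distinct spectrum of SRCR repeat copy-number alleles (short versus
long), and whether the repeat copy number propagates to transcript
length and salivary protein isoform size.

The package implements the full chain as reusable, tested components:

1. **selscan** — Tajima's D from phased haplotypes, a 10 kb
   non-overlapping window scan, z-normalization of a focal window
   against the genome-wide distribution, and a two-clade haplotype
   partition with tag-SNP selection.
2. **cnvphase** — PRT ratio to integer copy-number calling, phasing of
   multiallelic repeat alleles onto SNP haplotypes by pedigree
   constraint propagation, and a trio EM estimator of allele
   frequencies.
3. **assoc** — rank-sum association of clade with repeat alleles, a
   linear model of isoform size on diploid copy number and secretor
   status, and an expression-dosage trend test.
4. **txrepeats** — complete repeat-unit counting in long-read
   transcript exon chains.
5. **synthdata** — generators that emulate the statistical structure of
   every input, so the whole pipeline runs and is tested hermetically.

## The scan statistic

For a window with `n` haplotypes, `S` segregating sites and mean
pairwise diversity
$\hat\pi = \sum_{\text{sites}} 2 j (n-j) / (n(n-1))$
(`j` = derived count), Tajima's D is

$$D = \frac{\hat\pi - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}},$$

with the standard constants ($a_1 = \sum_{i<n} 1/i$, etc.) implemented
in `tajima_constants()`. Monomorphic sites are ignored; D is undefined
at `S = 0` and the window is flagged. Internally coordinates are
0-based half-open and a 1-based VCF position `p` falls in window
`floor((p-1)/w)`; conversion happens only at the I/O boundary, because
browser and VCF conventions differ and mixing them silently is the
classic off-by-one trap.

The focal window is z-normalized against the genome-wide distribution
of per-window D values: `z = (D - mean) / sd`, with the sample (n-1)
standard deviation over windows with defined D. Windows with fewer than
three variable sites are excluded — both as focal windows (reported
with an exclusion reason) and from the null moments, so near-monomorphic
windows cannot distort the calibration. The focal coordinates default
to the DMBT1 region (`dmbt1_region()`); `scan_dmbt1_region()` runs the
headline analysis on externally obtained population VCFs and is not
exercised hermetically.

Clade partitioning is complete-linkage agglomeration on pairwise
Hamming distance cut at two groups. The choice is deliberate: with two
deeply diverged clades, complete linkage is maximally conservative
about merging across the deep split, and ties are resolved
deterministically (labels normalized so `clade0` contains the
lowest-index haplotype). The tag SNP is the site with maximal
concordance (fraction of haplotypes matching their clade's majority
allele), ties broken leftmost; sites below concordance 0.5 are flagged
unreliable.

## The synthetic-data generator

`simulate_neutral_window()` is a bespoke Kingman/infinite-sites
simulator: exponential coalescence times with rate `j(j-1)/2`,
Poisson(θ/2 × branch length) mutations assigned to branches
proportionally to length, uniform distinct positions. It exists so the
genome-wide z-normalization has a hermetic null with the analytic
anchors `E[S] = θ a_1` and `E[D] ≈ 0`, which the tests check by
simulation.

`simulate_balanced_region()` builds the two-clade structure *directly*:
`round(f·n)` haplotypes form a "short" clade, `d` sites are planted as
fixed inter-clade differences, and each clade receives its own
coalescent mutations at rate `θ_within` over a 16.5 kb mock region. The
footprint being tested is a haplotype-structure pattern, not a
selection trajectory, so simulating selection dynamics would add
parameters without adding testability. The inter-clade divergence `d`
is a free parameter (real data do not pin it); the default is 20 fixed
differences.

`simulate_cnv_and_families()` draws per-haplotype repeat alleles from
clade-conditional spectra and pushes founder haplotypes through
Mendelian transmission in parent-offspring trios and three-generation
CEPH-style families (four grandparents, two parents, and a default
sibship of eight — the large sibships are what make reference-family
segregation analysis informative). The default spectra put the short
clade's mode at 8 repeats (with support down to the 7-repeat lower
bound) and the long clade's at 13, the qualitative separation reported
for European reference families; the short clade doubles as the
tag-SNP C allele. Diploid totals are reported with a ±1 error at a
configurable rate, because PRT miscalls are near-integer in practice.

What the generator does **not** emulate: recombination (within windows
or within the region), demography, per-population allele-frequency
differences, sequencing error, or read-level data. Two consequences
matter for interpreting green tests. First, a non-recombining 10 kb
coalescent window has a wider Tajima's D distribution (sd ≈ 0.9 at
n = 100, θ = 5) than real recombining genome windows, so the simulated
null's 99th percentile is conservative: a d = 20 / θ_within = 2 region
(D ≈ 2.4) clears `D > 1.5` essentially always but exceeds the simulated
null's 99th-percentile z only ~two-thirds of the time, whereas deeper
splits (d ≈ 40) clear it reliably. Real-data calibration, where
intra-window recombination shrinks Var(D), is expected to be more
favorable, but demonstrating that would need the recombination model
this package deliberately omits. Second, passing tests show the
machinery is correct on the assumed structure, not that real HGDP
windows satisfy that structure.

## Copy-number calling and phasing

`call_integer_cn()` fits a least-squares line CN = a + b·ratio per PRT
assay on calibration samples, averages per-sample estimates across
assays *before* rounding, rounds half away from zero, and flags calls
whose continuous estimate is more than 0.35 from an integer.

`pedigree_phase()` formalizes "phasing by observing segregation". Each
individual starts with every ordered allele pair `(h1, h2)` summing to
its diploid total within [kmin, kmax]; haplotype 1 is paternal for
non-founders. Two constraint families prune candidates to a fixpoint:
a child's paternal (maternal) allele must be placeable by the father
(mother) on a haplotype carrying the child's transmitted tag-SNP
allele, and conversely a parent's pair must be able to supply every
child. For families up to `exhaustive_limit` members a depth-first
enumeration of joint assignments then refines the propagated sets
exactly. Mendelian conflicts produce a named inconsistency report, not
an exception; an optional relaxation pass retries a family with a
single ±1 total adjustment and flags the rescued individual.

**Identifiability is the binding limitation.** When only diploid totals
and tag-SNP phase are observed, a family-wide shift that adds +s to one
haplotype and −s to its partner, propagated with alternating signs
along transmission paths, reproduces every total and every tag. Unique
resolution therefore comes only from boundary totals (e.g. 14 = 7+7 or
15 = 7+8 at the 7-repeat lower bound), from tag-identified
transmissions that force sign conflicts, and from their cascades. On
realistic spectra this resolves roughly a third of haplotypes in
three-generation families (and few in isolated trios) — always
correctly, in the sense that a resolved haplotype provably contains the
truth and the candidate sets match exhaustive enumeration exactly.
Laboratory studies escape the degeneracy by typing two smaller
copy-variable subregions separately; with totals-only input the
remaining ambiguity is irreducible, and the package reports it as
`ambiguous` status rather than guessing.

`trio_em()` estimates population allele frequencies from trios of
diploid totals under random mating with equiprobable transmissions, by
EM over per-trio configuration posteriors. The likelihood is multimodal
— totals are sums, so shifted allele supports can mimic each other —
and a single EM run from the uniform start can land on a symmetric
local optimum. The estimator therefore restarts from deterministic
quasi-random points on the simplex (default 10 starts) and keeps the
best final log-likelihood; within every run the log-likelihood is
asserted non-decreasing. A dense grid-search oracle over the 2-simplex
verifies the global optimum on small fixtures in the test-suite. MAP
per-trio configurations are reported with posteriors; ties go to the
lexicographically smallest configuration and are flagged.

## Association and the isoform model

`rank_sum_test()` uses mid-ranks, the tie-corrected normal
approximation and a 0.5 continuity correction — the appropriate regime
at the ~263-haplotype scale of the reference-family analysis — with a
complete-enumeration exact mode for pooled n ≤ 20. Two-sided
throughout. Population-level inputs take founder haplotypes only (two
per founder), because transmitted copies would be double-counted.

`isoform_model()` regresses salivary protein size on diploid SRCR copy
number, optionally with a secretor (Se) indicator, and reports Kendall's
rank correlation alongside. Western-blot band sizes make an ambiguous
response when a sample shows two bands (the heterozygous IV pattern
287/345 kDa), so the encoding is explicit: `mean_band` (default),
`largest_band` (the full-length glycoform), `smallest_band`, or
`class_rank`. On the bundled eight-sample panel the largest-band
encoding yields r² = 0.750 (overall p = 0.005) for the copy-number-only
model, and the mean-band encoding yields Kendall p = 0.004; with the
secretor indicator added (largest-band) r² rises to 0.82 and the
secretor coefficient is not significant (p ≈ 0.23). Secretor status
itself is the recessive FUT2 rule (`infer_secretor()`): homozygous null
→ Se−; the panel's FUT2 genotypes are reconstructed from the published
inferred statuses (2 Se− / 6 Se+) and marked synthetic in the
documentation. `dosage_trend_test()` pairs a one-way ANOVA across
rs-genotype classes with a two-tailed F test of the linear dosage term,
the design used for duodenal ddPCR expression panels.

## Transcript repeat counting

`count_repeat_units()` measures, for each annotated repeat unit, the
fraction of its length covered by a transcript's exons; a unit is
complete at ≥ 95% coverage (configurable), partially covered below
that. The 0.95 default separates "unit present" from alignment slop
without crediting half-units; counting is strand-agnostic and invariant
to splitting exons at internal points. A transcript is full-length when
both 5' and 3' mappable flags are set — the flags come from the
upstream read-processing toolchain (out of scope here) or from the
simulator, which truncates reads with a configurable probability.
`summarize_transcripts()` histograms complete-unit counts over
full-length transcripts and compares the mode (ties to the smaller
count, deterministically) with a genomic allele's unit count — the
comparison that shows transcript repeat number mirroring the
genetically encoded allele, e.g. a homozygous 11-repeat cell line
yielding transcripts counting 11 (with occasional 10s from minor
splicing variation).

## Numerical choices and problem sizes

- Half-integer copy-number estimates round away from zero; the 0.35
  quality threshold flags PRT calls in the ambiguous middle.
- All simulators consume a single integer seed; identical seed and
  configuration give bit-identical output (draw order is fixed:
  founders in pedigree order, haplotype 1 before 2, trios before
  three-generation families).
- EM convergence is a log-likelihood gain below 1e-8 with a 1000
  iteration cap per start.
- The test-suite exercises the stochastic claims at the scales the
  package's own calibration analyses use: 1000 neutral windows (n = 20,
  θ = 5) for scan calibration, a 400–500-window null with 200 balanced
  regions (n = 100) for detection, 100 error-free pedigrees for the
  phasing oracle, 500 trios for EM recovery, and 200 simulations of
  ~260 founder haplotypes for association power.

## Known limitations

- No recombination anywhere: the simulated genome-wide null for D is
  wider than a real recombining genome's, making z-detection of
  moderately diverged regions conservative (see above).
- Totals-only pedigree phasing leaves a large, irreducible ambiguous
  fraction; downstream population analyses use the resolved subset and
  log exclusions.
- The isoform model treats band size in kDa as the response; with eight
  samples the secretor term is estimated but not well powered.
- The transcript module consumes exon chains; basecalling, adapter
  handling, and spliced alignment are upstream tools' responsibility.
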