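# dmbtsel

Dissecting the balancing-selection footprint at the 5′ end of the human
**DMBT1** gene.

DMBT1 (gp340 / salivary agglutinin) binds bacteria through a tandem
array of SRCR (scavenger receptor cysteine-rich) domains whose repeat
number is polymorphic — individual alleles carry 7–21 units. The 5′
region of the gene shows one of the genome's strongest signatures of
balancing selection: two deeply diverged SNP haplotypes at intermediate
frequency. `dmbtsel` provides the analysis chain that links that SNP
footprint to the SRCR copy-number variation and its molecular
consequences, for population geneticists and genome scientists working
on multiallelic structural variation:

- **Selection scan** — Tajima's D from phased haplotypes,

  D = (π̂ − S/a₁) / √(e₁S + e₂S(S−1)),

  computed in 10 kb non-overlapping windows, with the focal window's D
  z-normalized against the genome-wide distribution (windows with fewer
  than three variable sites excluded); two-clade haplotype partitioning
  (complete-linkage on Hamming distance) and tag-SNP selection by
  maximal clade concordance.
- **CNV phasing** — PRT ratio → integer diploid copy-number calling;
  phasing of multiallelic repeat alleles onto SNP haplotypes by
  pedigree constraint propagation with exhaustive joint-assignment
  refinement (CEPH-style three-generation families), and a multi-start
  trio EM estimator of repeat-allele frequencies under random mating
  with equiprobable transmissions.
- **Association & isoform model** — tie-corrected Wilcoxon rank-sum
  test (continuity-corrected normal approximation; exact mode for small
  n) of repeat alleles on A- vs C-tagged haplotypes; OLS of salivary
  isoform size (kDa) on diploid SRCR copy number ± FUT2 secretor
  status, with Kendall rank correlation; ANOVA + linear dosage trend
  for expression panels.
- **Transcript repeats** — complete SRCR unit counting in long-read
  transcript exon chains against a genomic repeat annotation
  (coverage ≥ 0.95 per unit), with full-length classification and
  modal-count comparison against the genomic allele.
- **Synthetic data** — a Kingman/infinite-sites coalescent simulator,
  a structural two-clade balanced-region generator, clade-linked CNV
  spectra pushed through simulated trios and three-generation
  pedigrees, isoform panels, and truncation-aware transcript reads, so
  every stage runs and is tested with no downloads.

## Worked example

```r
library(dmbtsel)

## a 16.5 kb region carrying two divergent clades (n = 100 haplotypes,
## 20 fixed inter-clade differences, within-clade theta = 2)
sim <- simulate_balanced_region(100, clade_freq = 0.5,
                                clade_divergence = 20,
                                theta_within = 2, seed = 7)
region <- tajimas_d(sim$hapmat)
region
#> window_stat chr10:122555561-122571917  n=100  S=37  pi=12.9473  thetaW=7.1465  D=2.5195

## z-normalize against a simulated genome-wide null
set.seed(7)
null_windows <- do.call(rbind, lapply(1:400, function(i) {
  ws <- tajimas_d(simulate_neutral_window(100, theta = 5))
  data.frame(S = ws$S, D = ws$D)
}))
znormalize(region, null_windows)
#> zscan: z = 2.812 against 400 windows (mean -0.067, sd 0.920)

partition_clades(sim$hapmat)
#> clade_partition: 50 | 50 haplotypes; between = 24.06, within = 1.61; 20 concordant site(s)
#>   tag SNP at 122557171 (concordance 1.000)

## phase repeat alleles through simulated families and test the
## clade-vs-copy-number association on resolved founder haplotypes
cfg <- sim_config(seed = 7, n_trios = 66, n_pedigrees = 10,
                  cn_measurement_error = 0)
fam <- simulate_cnv_and_families(cfg)
phased <- pedigree_phase(fam$pedigree, fam$cn_obs, fam$snp_phase,
                         exhaustive_limit = 16)
phased
#> pedigree_phasing: 676 haplotypes (142 unique, 534 ambiguous)
rec <- attach_to_haplotypes(phased)
clade_association_test(rec)
#> rank_test (normal): W = 136.0, z = 3.118, p = 0.001823 (n = 10 + 16)

## the bundled eight-sample salivary isoform panel
panel <- dmbt1_isoform_panel()
isoform_model(panel, response = "largest_band")
#> isoform_fit (largest_band, n = 8): r^2 = 0.750, overall p = 0.005444; Kendall tau = 0.840 (p = 0.007661)
table(infer_secretor(panel$fut2_genotype))
#> Se- Se+
#>   2   6

## transcript repeat counting for an 11-repeat allele
gm <- dmbt1_gene_model()
reads <- simulate_transcript_reads(gm, true_unit_count = 11,
                                   n_reads = 1000,
                                   truncation_rate = 0.3, seed = 7)
counts <- lapply(reads, count_repeat_units, ann = gm$annotation)
summarize_transcripts(counts, genomic_allele = 11)
#> transcript_summary: 700/1000 full-length; mode = 11
#>   complete-unit histogram: 11:700
#>   genomic allele 11: concordant
```

Reading the numbers: the deep 50/50 clade split drives D to ~2.5 —
far into the upper tail of the neutral null (z ≈ 2.8) — and a single
perfectly concordant SNP tags the clades, mirroring the role of
rs11523871. Pedigree phasing resolves the identifiable subset of
haplotypes (diploid totals alone under-determine the rest; resolved
calls are exact), and the resolved founder haplotypes show the
short-allele enrichment on C-tagged haplotypes. On the isoform panel,
diploid SRCR copy number explains 75% of protein-size variation. Of
1000 simulated long reads at 30% truncation, the ~700 full-length ones
all count the encoded 11 repeat units.

Real-data entry points: `read_phased_vcf()` (phased population VCFs),
`read_pedigree()` / `read_cn_table()`, `read_repeat_annotation()` /
`read_transcript_alignments()` (BED/GFF3), and `scan_dmbt1_region()`
for the GRCh38 chr10:122555466–122571966 region on externally obtained
genotypes.

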