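# amplimeth

Promoter CpG-island methylation analysis of the TRAIL death-receptor genes
*DR4* (*TNFRSF10A*) and *DR5* (*TNFRSF10B*) from targeted bisulfite amplicon
sequencing, for epigenomics researchers studying TRAIL resistance in
leukemia.

Hypermethylation of the CpG islands at the *DR4*/*DR5* promoters silences
the receptors and makes leukemia cells resistant to TRAIL-mediated killing —
the effector mechanism shared by CAR T-cells, bispecific T-cell engagers and
the graft-versus-leukemia effect. This package implements the full
quantitative pipeline around that question:

- **In-silico bisulfite PCR** (`in_silico_pcr`): finds the amplicon a
  CG-free, bisulfite-space primer pair produces from an unconverted genomic
  top strand, by matching the forward primer and the reverse complement of
  the reverse primer on the fully converted (C→T) sequence.
- **Bisulfite-aware methylation calling** (`quantify_methylation`): global
  alignment of each read against the unconverted amplicon under four
  hypotheses — read as given or reverse-complemented, scored with a
  top-strand model (reference C matches read C/T free) or a bottom-strand
  model (reference G matches read G/A free) — followed by per-read per-CpG
  calls (retained C ⇒ methylated), QC filtering on identity, non-CpG
  conversion efficiency and length, and per-site tallies. The amplicon
  summary is the **unweighted mean percent methylation across CpG sites**,
  `100·M/(M+U)` per site.
- **Classification** (`classify_methylation`, `classify_trail`,
  `methylation_band`): the four-way partition of the (DR4%, DR5%) plane at
  the 1% threshold, the highly-methylated flag (both ≥ 10%), TRAIL
  sensitivity bands on percent inhibition (≥ 80 sensitive, < 25 resistant),
  and the unmethylated/weak/high bands ([0,1), [1,10), [10,100]).
- **Association statistics** (`spearman_cor`, `mann_whitney`,
  `fisher_exact`, `chi_square`, `associate_panel`): Spearman rank
  correlation reported with R² = rho², exact Mann–Whitney at small n,
  two-sided Fisher and Pearson chi-square tests.
- **450k-style cohort aggregation** (`select_probes`, `gene_methylation`,
  `subtype_summary`, `paired_delta`, `analyze_cohort`): per-gene selection
  of probes annotated TSS200 ∩ CpG island, per-sample percent methylation
  as 100 × mean beta, karyotype-subtype counts of samples ≥ 10%, and paired
  diagnosis/relapse changes.
- **Simulators** (`simulate_reads`, `simulate_panel`,
  `simulate_array_cohort`): bisulfite reads with known per-CpG truth
  (incomplete conversion, inappropriate conversion, substitution error,
  both strands), a 32-line cell panel with karyotype-dependent methylation
  priors, and an array cohort with subtype-dependent hypermethylation —
  every pipeline stage is testable without external data.

## Worked example

```r
library(amplimeth)

amp <- synthetic_amplicon("DR4_like", n_cpg = 6, seed = 42)
amp
#> Amplicon 'DR4_like': 136 bp, 6 CpG sites
#>   fwd primer: AAAAGGGATTAAGGGTTAAT
#>   rev primer: CCTTCCCCAACCTCACTTAT
#>   CpG offsets (0-based): 32, 46, 60, 74, 88, 102

profile <- c(0, 0, 0.30, 0.30, 0.90, 0.94)   # true per-site methylation
sim <- simulate_reads(amp, profile, read_sim_params(n_reads = 2000, seed = 1))
res <- quantify_methylation(sim$reads, amp)
summary(res)
#> Methylation call for amplicon 'DR4_like'
#>   reads: 2000 total, 1998 passing QC (failed: identity 0, conversion 2, length 0)
#>   mean percent methylation: 41.05%
#>   per-site summary:
#>  site_index offset coverage n_methylated    percent
#>           1     32     1993           19  0.9533367
#>           2     46     1994            9  0.4513541
#>           3     60     1993          604 30.3060712
#>           4     74     1991          634 31.8432948
#>           5     88     1992         1773 89.0060241
#>           6    102     1997         1872 93.7406109
```

Every estimate sits within ~1–2 percentage points of its truth; the small
positive bias at unmethylated sites is the expected `(1 − conversion rate)`
inflation from incomplete bisulfite conversion, which is reported raw, not
corrected. Classifying this sample together with an unmethylated *DR5*
measurement:

```r
classify_methylation(res$mean_percent, 0.8)
#>          category highly_methylated
#> 1 DR5_PREF_UNMETH             FALSE
```

A cohort-scale run (459 diagnostic samples across nine karyotype subtypes):

```r
cohort <- simulate_array_cohort(cohort_gen_params(seed = 1))
cres <- analyze_cohort(cohort$beta, cohort$samples, cohort$annotation)
cres$summaries$DR4$overall
#> DR4 >=10%: 5/459 (1.1%)
cres$correlation
#> Spearman rho = 0.447 (R^2 = 0.200), p = 5.942e-24, n = 459
```

Promoter hypermethylation is rare at diagnosis and concentrated in the
unfavorable karyotypes (dic(9;20), *MLL*-rearranged, hypodiploid), while
the two genes' methylation levels correlate positively across samples.

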