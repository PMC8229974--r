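---
title: "Methods: bisulfite amplicon methylation calling and TRAIL-sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bisulfite amplicon methylation calling and TRAIL-sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimeth)
```

# The measurement problem

Bisulfite treatment converts unmethylated cytosine to uracil (read as T
after PCR) while 5-methylcytosine is protected. Sequencing a bisulfite-PCR
amplicon therefore turns methylation into a base call: at a CpG cytosine, a
retained C means methylated, a T means unmethylated. amplimeth quantifies
per-CpG methylation of promoter CpG-island amplicons — built around the
death-receptor genes *DR4*/*DR5*, whose silencing confers TRAIL resistance
in B-cell precursor acute lymphoblastic leukemia — and carries the
estimates through classification, association statistics and
methylation-array cohort aggregation.

# In-silico bisulfite PCR

Primers for bisulfite PCR are designed against the *converted* sequence and
must not span a CG dinucleotide, otherwise the primer's binding would
depend on the methylation state it is supposed to measure
(`validate_primer` enforces this). Because valid primers are CG-free, the
fully converted top strand (every C read as T) is methylation-independent
at the binding sites, so `in_silico_pcr` searches it directly: the leftmost
forward-primer match (configurable mismatch allowance, default 0; N never
matches) is paired with the nearest downstream match of the
reverse-complemented reverse primer, and the primer-inclusive product is
mapped back to the unconverted input, where CpG offsets are computed.
Coordinates are 0-based half-open throughout. More than one product under
the size cap (default 2000 bp) is reported as ambiguous amplification
rather than silently picking one. A `strand = "bottom"` mode searches the
reverse complement of the input, so a locus supplied in either orientation
yields the same amplicon.

# Read alignment and calling

A bisulfite read may originate from either strand. In top-reference
orientation, top-strand reads show C→T conversions and bottom-strand reads
show G→A conversions. `align_reads` scores each read under four hypotheses
(read as given / reverse-complemented × top model / bottom model) with
asymmetric substitution scoring: match +1, mismatch −1, and the bisulfite
pair (reference C with read T, or reference G with read A) at full match
score; gaps cost −2 per base, linear. The best-scoring hypothesis fixes
the strand.

Numerically, reads whose length equals the reference are scored by the
ungapped alignment — optimal whenever differences are substitutions, which
is the regime targeted amplicon reads live in — and fall back to the full
gapped alignment (via Biostrings) when the ungapped score drops below half
the reference length or the lengths differ. Ties between hypotheses are
resolved toward the top model; a perfectly methylated, error-free read is
the only common case where both models tie, and its calls are identical
under either.

Per-read calls (`call_reads`) read the base at each CpG position: C→M,
T→U, anything else (including gaps) → N on the top strand; G→M, A→U, else
N on the bottom. Two per-read QC statistics follow:

- **conversion efficiency** — the fraction of non-CpG reference cytosines
  (top) or guanines (bottom) observed converted, among positions observed
  in either state. Non-CpG cytosines are assumed unmethylated, so this
  estimates the bisulfite conversion rate of the individual molecule.
- **identity** — the match fraction over aligned positions whose reference
  base is not bisulfite-ambiguous under the chosen model.

`filter_reads` passes a read iff identity ≥ 0.90, conversion efficiency
≥ 0.90 and length ≥ 50; failures are tallied under the first failing rule
in that order. These defaults are the package's own: vendor pipelines for
this assay do not document their internal filters, so amplicon-level
results from real instruments can be emulated but not reproduced
bit-exactly.

`summarize_calls` tallies M and U per site, ignoring N calls per site
rather than dropping whole reads (maximizing usable coverage), reports
percent methylation `100·M/(M+U)` for sites with ≥ 100 informative calls
(configurable), and averages **unweighted** across qualifying sites — the
amplicon summary is a mean over CpG sites, not over reads. No
conversion-rate correction is applied: incomplete conversion at rate
`1 − c` inflates an unmethylated site's estimate by about `100·(1 − c)`
percentage points (≈ 0.5 points at the default c = 0.995), which is
documented rather than corrected because the field reports raw percents.

# Classification thresholds

The (DR4%, DR5%) plane is partitioned at 1%: both < 1 unmethylated; DR4 < 1
≤ DR5 DR4-preferentially unmethylated; DR5 < 1 ≤ DR4 DR5-preferentially
unmethylated; both ≥ 1 methylated. Samples with both genes ≥ 10% carry the
highly-methylated flag; the 10% boundary is inclusive everywhere (the
cohort-level convention, applied uniformly). TRAIL response at 100 ng/mL
rhsTRAIL is banded on percent inhibition: ≥ 80 sensitive, < 25 resistant,
otherwise intermediate; the three-way scheme is used without further
subdivision of the intermediate range. Percent inhibition is
`100·(1 − treated/untreated)` thymidine uptake, with negative values
(growth stimulation) retained down to −100 so rank tests see honest
orderings; RFI is the specific-to-control ratio of mean fluorescence
intensities.

# Statistics

Percent methylation spans orders of magnitude, so associations use
`log10_percent`: log10 of the percent floored at 0.1%. The floor exists
because at the default 100× coverage requirement, percents below
1/coverage are indistinguishable from zero; Spearman statistics are
invariant to any strictly increasing transform, so the floor only affects
how zeros tie.

- `spearman_cor`: rho is the Pearson correlation of average (tie-corrected)
  ranks; the two-sided p uses the t approximation
  `t = rho·sqrt((n−2)/(1−rho²))` on n−2 df. The squared coefficient is
  reported alongside as R², the convention used for rank correlations in
  this literature.
- `mann_whitney`: U from rank sums with average ranks. For n1+n2 ≤ 10 the
  two-sided p is exact by full enumeration of rank assignments (valid under
  ties); beyond that, the normal approximation with tie and continuity
  corrections. The exact path agrees with the corrected approximation to
  within 0.05 at n1 = n2 = 5.
- `fisher_exact` / `chi_square`: the standard two-sided hypergeometric rule
  (sum of tables no more probable than the observed) and the Pearson
  statistic without continuity correction, both via the stats package and
  cross-checked against enumeration oracles in the test suite.

Two-sided tests throughout; no multiple-testing correction is applied (none
is conventional for this handful of pre-specified comparisons, and the
reported p-values are interpretable as-is).

# What the simulators emulate

**Reads** (`simulate_reads`): each read is a full-length single-molecule
copy of one strand (top with probability `frac_top_strand`, default 0.5).
Per read, each CpG's methylation state is Bernoulli with the site's profile
value; unmethylated cytosines convert with probability `c` (default 0.995,
a typical commercial-kit conversion rate), methylated CpG cytosines
erroneously convert with probability 0.005, and a uniform 0.005 per-base
substitution error is applied afterwards. Bottom-strand reads are emitted
as the reverse complement of the converted bottom strand, i.e. in the
orientation that shows G→A conversions against the top reference. No
published error rates exist for the emulated runs; these defaults are
stipulated, not fitted. Sites are independent within a read by default —
consistent with the near-uniform per-site levels targeted amplicons show
within a sample — with an optional `epiallele_cor` parameter (shared
latent uniform per read) for coupled epialleles; it defaults to 0.
Quality strings are constant Q30 since calling does not use qualities.
Not modeled: indel (homopolymer) errors of semiconductor sequencing, PCR
duplicates and amplification bias. Passing tests therefore demonstrate
correctness of the calling arithmetic and QC logic, not robustness to
instrument-specific artifacts.

**Cell panel** (`simulate_panel`): 32 lines across seven karyotype groups
(9 MLL-rearranged, 6 BCR-ABL1, 7 TCF3-PBX1, 4 TCF3-HLF, 2 ETV6-RUNX1, 2
MEF2D-rearranged, 2 DUX4-rearranged). Each gene's methylation fraction is a
two-component mixture: a methylated component Beta(8, 2) (mean 0.8 —
silenced promoters are densely methylated) entered with a
karyotype-dependent probability (1.0 for MLLr/MEF2Dr DR4, 0 for TCF3-HLF
and ETV6-RUNX1), and an unmethylated component Beta(0.8, 150) (mean
≈ 0.5%). The two genes' levels share a Gaussian-copula correlation of 0.7
within a line (a line-wide silencing propensity), reproducing the positive
between-gene methylation correlation seen across such panels. Downstream,
log10 relative expression is `α − β·m` + N(0, σ_E) with α = 0, β = 2,
σ_E = 0.25; RFI is 1 plus a gain (4) times relative expression with
log-normal noise; and percent inhibition follows a logistic link on
receptor availability `s = max(1 − m_DR4, 1 − m_DR5)` — either receptor
suffices for apoptosis — `100·logistic(θ(s − s0))` with θ = 10, s0 = 0.5,
plus N(0, 5) noise clipped to [−10, 100]. Under these settings doubly
hypermethylated lines are almost always TRAIL-resistant and unmethylated
lines sensitive, matching the structure such panels exhibit.

**Array cohort** (`simulate_array_cohort`): 459 diagnostic samples with the
subtype composition of a large childhood BCP-ALL cohort (187
high-hyperdiploid, 164 ETV6-RUNX1, 23 TCF3-PBX1, 10 iAMP21, 20 dic(9;20),
19 BCR-ABL1, 28 MLLr, 5 hypodiploid, 3 polyploid), plus 20 remission
samples and 24 diagnosis/relapse pairs. Gene-level beta values are
hypermethylated (truncated normal, mean 0.30, ≥ 0.15) with a per-subtype
probability set from the observed frequencies (DR4: 1/23 TCF3-PBX1, 1/20
dic(9;20), 2/28 MLLr, 1/5 hypodiploid; DR5: 5/20, 10/28, 1/5; zero
elsewhere), otherwise baseline 0.025 ± (0.006 shared per sample + 0.005
per gene), truncated to ≤ 0.08 — so remission samples sit at the 2–3%
background the assay shows in normal hematopoiesis, and hypermethylated
samples are separated from baseline across the 10% reporting threshold by
construction (per-probe jitter sd 0.01 cannot bridge the gap, which is
what lets tests compare threshold counts against truth labels exactly).
The shared baseline component couples the two genes' low-level methylation
(array-wide sample effects), giving the cohort-scale positive between-gene
correlation; `share_hyper` couples the hypermethylation events themselves
(default on). Relapse samples gain hypermethylation with probability 0.2
per gene when unmethylated at diagnosis. The annotation carries 6 DR4 and
5 DR5 probes marked TSS200 + Island plus decoys (other feature groups,
island relations and genes) that the selection rule must reject. Probe
selection, missing-beta handling (pairwise exclusion; a sample is missing
only if all its probes are) and the 100×-mean-beta percent convention
follow the standard 450k workflow; raw IDAT processing and normalization
are out of scope — betas are consumed as provided.

# Pipeline and determinism

`run_pipeline` composes simulate → call → classify → associate → cohort
from one serializable JSON config, writing every stage's TSV/JSON outputs
and a manifest (package version, seed, config hash). Stage seeds derive
from the master seed by fixed offsets, so a run re-executed from its
emitted config is byte-identical; any stage error aborts naming the stage.
All artifacts are plain text; plotting, when wanted, renders from the TSVs
and never feeds back into results.

# Problem sizes

The shipped tests and the acceptance script use 1000–2000 reads per
amplicon (giving ~1–2 percentage-point accuracy at 100× minimum coverage,
comfortably resolving the 1% and 10% thresholds), the 32-line panel, and
the 459 + 20 + 48-sample cohort; the Fisher oracle sweep covers all 2×2
tables with total ≤ 20. These sizes were chosen so each property is tested
at the scale the thresholds demand while the whole suite stays fast.

# Known limitations

- Amplicon-level results from real sequencing runs can be emulated but not
  reproduced bit-exactly: vendor calling filters are undocumented, and the
  published panel measurements underlying the cell-line associations are
  not publicly released.
- The aligner models substitutions and uniform gaps only; flow-space
  homopolymer error structure is not represented.
- Applying the pipeline to a real 450k cohort requires mapping the vendor
  manifest to the annotation columns used here (probe id, gene, UCSC
  feature group, relation to island); annotation-version differences can
  change which probes the TSS200 ∩ Island rule selects.
- Estimates are raw: no conversion-bias correction, no deconvolution of
  normal-cell contamination (which dilutes clinical-sample methylation).
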