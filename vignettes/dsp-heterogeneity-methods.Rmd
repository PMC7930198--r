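---
title: "Models and methods: DSP phenotype heterogeneity analysis"
author: "dspHet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: DSP phenotype heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(dspHet)
  library(SummarizedExperiment)
})
```

# Scope

`dspHet` implements the count-processing and heterogeneity statistics used
to analyze GeoMx-style digital spatial profiling (DSP) of multi-region
tumor cohorts: barcoded probes are hybridized in situ, released from
user-selected regions of interest (ROIs, 200–500 µm circles) and counted
by sequencing. Per patient, several anatomically distinct metastases are
sampled, and several spatially distinct ROIs per metastasis, producing a
patient / tumor / ROI hierarchy over which intra-tumor, intra-patient and
inter-patient phenotype concordance can be quantified. Every stage is also
exercised by a seeded synthetic generator, so the full pipeline is testable
without any external data.

# Data containers

Probe-level counts live in a `ProbeCountSet` and collapsed gene or antibody
counts in a `TargetCountSet`; both extend `SummarizedExperiment`, with ROI
annotations (hierarchy ids, tissue class `T`/`TS`/`ST`/`S`, CD3+ counts,
tumor/stroma percentages, QC flags) in `colData`. Counts tables are
exchanged as TSV, annotations as CSV, gene sets as GMT, and alignment
records as a 5-column SAM text subset.

# Probe collapsing

Each gene is measured by several probes (median 10 in the emulated panel).
Per gene and per ROI, probes whose `log2(count + 1)` is an outlier under an
iterative two-sided Grubbs test at $\alpha = 0.01$ are removed; groups of
fewer than three probes are never tested, so a gene can never lose all of
its probes. The collapsed gene count is the geometric mean of the retained
probe counts. The Grubbs critical value is

$$G_{crit}(n, \alpha) = \frac{n-1}{\sqrt{n}}
  \sqrt{\frac{t^2_{\alpha/(2n),\,n-2}}{\,n-2+t^2_{\alpha/(2n),\,n-2}}}.$$

*Numerical choice.* Everywhere a geometric statistic is taken on raw
counts, counts are floored at 1 before the log (`geoMean()`), so zero
counts neither produce $-\infty$ nor perturb typical data; the Grubbs
screen uses the `log2(count + 1)` scale. A per-ROI (rather than global
per-probe) outlier rule was chosen because corruption in these assays is
typically a local segment artifact.

# Limits of quantitation and detection

The RNA limit of quantitation is derived per ROI from the raw negative
probes: with $\mu$ and $\sigma$ the mean and SD of their log counts,

$$\mathrm{LOQ} = e^{\mu + 2\sigma}
             = \mathrm{geomean} \times \mathrm{GSD}^2,$$

i.e. "geometric mean plus two standard deviations" read on the log scale.
The protein LOQ is $3\times$ the per-ROI geometric mean of the IgG control
antibodies. A target is *detected* when its count is strictly above the
LOQ ("above" read literally, making the boundary testable); antibody
detection alternatively uses the signal-to-noise ratio
$\mathrm{SNR} = \mathrm{count} / \mathrm{geomean(IgG)}$ with an inclusive
cutoff at 3 (a value *below* 3 is not detected), guarded by a $10^{-12}$
relative tolerance against floating-point noise in the log-space geometric
mean.

QC filtering removes ROIs flagged missing/fat, purely stromal or
sequencing failures, then ROIs with $\le$ `minGenes` (default 100)
detected genes, then genes detected in no retained ROI; the attrition
ledger reports one count per reason and always sums to input minus
retained.

# Normalizations

All normalizations are per-ROI scalar multiplications and therefore
preserve within-ROI rank order:

* **Negative normalization (NN):**
  $\log_2(\mathrm{count}/\mathrm{geomean(negatives)})$ — background sits
  at 0 and a doubling adds exactly 1.
* **Q3:** each ROI divided by the 75th percentile of its detected counts
  (linear-interpolation percentile, `quantile` type 7, fixed for
  reproducibility) and rescaled by the geometric mean of all ROIs' Q3s.
  Each ROI needs at least 4 detected targets. Note that rescaling by the
  cohort geometric mean makes single-ROI rescaling exactly neutral only up
  to the factor $c^{1/R}$ that the scaled ROI contributes to the global
  constant.
* **Housekeeping:** each ROI divided by the geometric mean of the three
  reference proteins (RPS6, histone H3, GAPDH in the emulated panel) and
  rescaled by the cohort geometric mean of those factors.

# Signature scores and the six phenotype classes

For a gene set of size $k$, each gene is z-scored across samples and the
per-sample score is the combined z-score $\sum_i z_{ij} / \sqrt{k}$.
Zero-variance genes are dropped from $k$; if all are dropped the score is
0 (`combinedZScore()` implements exactly this, and its scores sum to zero
across the cohort).

Because $\sum z/\sqrt{k}$ scales with $\sqrt{k}$, `scoreSignatures()`
additionally rescales each signature's scores to unit SD across the
scoring cohort by default. This is a deliberate design choice: the
classification thresholds below are expressed in cohort-standardized
z-units and would otherwise have to depend on the signature size.

ROIs (or tumors, after averaging their ROI scores first) are classified on
the AR and NE axes: positive at or above `high` (default $+0.5$; the
boundary classifies upward), low in `[low, high)` (default low $= -0.5$),
negative below `low`. The nine combinations fold onto the six printed
classes AR+/NE−, ARlow/NE−, AR−/NE−, AR−/NElow, AR+/NE+ and AR−/NE+:
sub-threshold activity on one axis under a positive call on the other is
read as negative on that axis (AR+/NElow → AR+/NE−, ARlow/NE+ → AR−/NE+,
ARlow/NElow → ARlow/NE−).

*Known limitation.* Threshold classification on cohort-standardized
scores is sensitive to the cohort's class composition: under a heavily
skewed mix (e.g. 60% AR+/NE−) the standardized mean of a minority class
can straddle a fixed threshold. On balanced synthetic cohorts at effect
size 2 log2-units the defaults recover ≥ 90% (typically ~99%) of planted
phenotypes; on the skewed default mix the ARlow class sits near the lower
threshold and recovery degrades. The thresholds are fully configurable and
were validated by parameter recovery on synthetic data only — they are not
claimed to reproduce any particular study's per-sample calls, whose exact
MDS-based assignment procedure is not specified operationally.

Classical MDS (`classicalMds()`, a thin layer over `stats::cmdscale` with
Euclidean distances) is retained for visualization: signs are fixed so
each coordinate's largest-magnitude entry is positive, and exact
configurations of intrinsic dimension ≤ 2 are reproduced to machine
precision.

# Concordance statistics

ROI pairs are stratified as intratumor (same tumor), intrapatient (same
patient, different tumors — excluding same-tumor pairs keeps the three
strata disjoint and their ordering meaningful) and interpatient. Exact
pair agreement enumerates all nonmissing pairs; over a whole sample set
it equals the hypergeometric identity
$\sum_g \binom{n_g}{2} / \binom{n}{2}$ over the class sizes $n_g$.
Sampled agreement draws pairs uniformly with replacement and is unbiased
for the exact value.

Uncertainty is quantified by bias-corrected and accelerated (BCa)
bootstrap intervals from $B = 1000$ replicates. The resampling unit is
the **patient** (cluster bootstrap): resampling ROIs directly would break
the within-patient correlation structure and understate between-patient
variance. The bias term is $z_0 = \Phi^{-1}(p_0)$ with $p_0$ the fraction
of replicates below the point estimate (ties counted half, which handles
the discreteness of agreement proportions symmetrically, and $p_0$ clamped
to $[1/2B,\ 1 - 1/2B]$); the acceleration is the jackknife skewness
$a = \sum u^3 / (6 (\sum u^2)^{3/2})$ with $u$ the leave-one-patient-out
deviations; endpoints are read from the bootstrap distribution by inverse
ECDF (order statistic at $\lceil B p \rceil$). A degenerate bootstrap
distribution yields a zero-width interval with a warning. Empirical
coverage is checked by simulation in the test suite (500 replications of
26-patient Bernoulli-agreement cohorts).

Profile-level heterogeneity uses per-pair Pearson correlations of
expression vectors labeled by stratum (zero-variance profiles skipped and
counted), and per-gene group comparisons use two-sided Wilcoxon rank-sum
tests (exact for small tie-free groups, so complete separation of 6 vs 3
samples gives $p = 2/\binom{9}{3} \approx 0.024$) with Benjamini–Hochberg
adjustment across genes.

# AR-V7 junction quantification

AR-V7 transcripts include cryptic exon 3; spliced alignments across the
exon3–CE3 junction appear as reference-skipping gaps. A record counts if
it lies on the junction chromosome and has at least one gap (CIGAR `N`,
or a deletion of ≥ 20 bases — long deletions in spliced aligners are
junction-equivalent) whose donor (last aligned base before the gap) and
acceptor (first aligned base after) both fall inside
chrX:67686127–67694672 (1-based inclusive). Records are deduplicated by
read id; malformed CIGARs are skipped and tallied. The count is
normalized to spliced reads per million,
$\mathrm{SRPM} = \mathrm{count}/(\mathrm{total\ aligned\ reads}/10^6)$;
the denominator is taken as total aligned reads (the natural reading of
"per million"; a spliced-reads-only denominator would not be computable
from the junction records alone).

# The synthetic generator

The generator's defaults are the emulated study conditions: 26 patients ×
2 tumors × 3 ROIs; a 2093-gene panel with a median of 10 probes per gene
and 220 negative probes; a 57-antibody panel with 3 IgG controls and 3
housekeeping proteins. Counts follow a multiplicative lognormal model

$$\mathrm{count} = \mathrm{round}\!\left(d_r \cdot b_g \cdot
  2^{\,e\,a_{gr}} \cdot \varepsilon\right),$$

with per-ROI depth $d_r$ (geometric SD 2 by default), per-gene baseline
$b_g$ (lognormal, geomean 25, geometric SD 4 — wide, so that only a
minority of genes clears the LOQ on a typical ROI, reproducing the
order-of-magnitude count range and partial detection seen on tumor ROIs),
effect size $e$ (2 log2-units), activity $a_{gr} \in \{0, 0.5, 1\}$ from
the planted phenotype, and probe noise $\varepsilon$ (geometric SD 1.6).
Negative probes share a phenotype-independent background (geomean 20 at
unit depth). Outlier corruption multiplies 1% of (probe, ROI) cells by
20×, exercising the Grubbs path. Discordance is planted per patient
(fraction 0.27 of patients carry a discordant second tumor, matching 7/26)
and per tumor (0.04 carry one discordant ROI, matching ~2/53).

What the generator does *not* emulate: spatial autocorrelation within a
tumor section, cell-type mixture within an ROI, probe-sequence-specific
efficiency, batch/slide effects, and count overdispersion beyond the
lognormal. Passing tests therefore demonstrate the correctness of the
statistics under the stated model, not robustness to every artifact of
real slides.

# Problem sizes and reproducibility

The test suite runs on reduced panels (~120–300 genes, 4–8 probes per
gene, 20–60 negatives) and cohorts of 2–20 patients, chosen so each test
isolates one property at a comfortable signal size; the acceptance script
runs the full 2093-gene, 156-ROI design. Every stochastic operation takes
an explicit integer seed and records it in its output; identical
configuration and seed give byte-identical results.
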