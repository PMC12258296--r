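---
title: "Cross-platform transcriptome concordance: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform transcriptome concordance: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xconcord)
```

## The problem

Archival formalin-fixed, paraffin-embedded (FFPE) tissue is abundant in
pathology archives but yields fragmented RNA. Two technologies tolerate that
degradation well: 3′-tag RNA sequencing, which counts one short fragment near
each transcript's polyadenylated end across the whole transcriptome, and
direct hybridization counting panels, which digitally count a fixed set of
~800 probes without reverse transcription or amplification. When both are run
on RNA from the *same* isolation batches, how well do they agree — per sample,
per gene, and in the differential-expression calls a study would actually
report?

`xconcord` implements that comparison as a reusable pipeline: normalization
(CPM, TMM, RLE on the sequencing side; two-step positive-control/housekeeping
normalization on the panel side), sample-wise and gene-wise correlation
profiling with expression strata, a self-contained negative-binomial
differential-expression engine with fold-change shrinkage and BH/BY
adjustment, and a concordance layer (annotation overlap, log2FC correlation,
direction classes, Venn counts, Jaccard index). A paired-platform simulator
with known ground truth makes every stage testable with no external data.

## The simulator's stated world

One call to `simulate_paired_study()` draws a single latent truth and two
platform measurements of it. For gene $g$ in sample $s$ on a platform, the
expected count is

$$\mu_{gs} = 2^{\,b_g + \beta_g\,[s \in B] + \ell_{gs} + c_g + d_s + \varepsilon_{gs} + o}$$

and the observed count is negative binomial with variance
$\mu + \phi\mu^2$. The components are:

* $b_g$ — per-gene baseline log2 expression, $N(4, 2^2)$ by default;
* $\beta_g$ — true log2 fold change (group B vs A), nonzero for a
  `de_fraction` of genes (default 10%), drawn $N(0, 1.5^2)$;
* $\ell_{gs}$ — **shared** biological sample-to-sample variation,
  $N(0, 0.7^2)$, identical for both platforms because both measure the same
  RNA. This is the signal that gene-wise correlations recover; without it a
  non-DE gene has nothing in common between platforms across samples.
  0.7 log2 units is a typical tumor-tissue biological spread;
* $c_g$ — per-gene capture/probe efficiency, drawn once per platform
  (sd 0.5): systematic 3′-bias or probe affinity that shifts a gene's level
  on one platform but cancels out of within-platform group contrasts;
* $d_s$ — per-sample depth (sd 0.25–0.3 log2); $o$ a global depth offset,
  +4 log2 units for sequencing and +2 for the panel, placing simulated
  library sizes near the reported ~5 million trimmed reads per sample and
  typical digital-counting levels respectively;
* $\varepsilon_{gs}$ — per-observation platform noise (sd 0.1–0.15);
* $\phi$ — NB dispersion, 0.15 for sequencing, 0.05 for the panel
  (digital counting is tighter); $\phi = 0$ gives Poisson counts.

The default design mirrors a two-group tumor contrast with 10 vs 11 samples,
20,000 annotated genes, and a panel of 780 endogenous plus 20 housekeeping
genes (drawn from non-DE genes only), 6 positive controls with fixed means
spanning four orders of magnitude ($10^1$–$10^5$, scaled by lane depth), 8
negative controls (Poisson, mean 2), and 9 panel genes (~1%) absent from the
sequencing annotation. Panel probes additionally receive a Poisson(2)
hybridization background — the floor the negative controls measure — which
keeps low-expression probe counts off zero, as real panel data are.

Two deliberate structural choices:

* The **missing** genes are kept in the panel matrix but removed from the
  sequencing matrix: a panel measures its probes regardless of what the
  genome annotation contains, so the annotation gap must show up on the
  sequencing side for the overlap accounting to be meaningful.
* A single master seed spawns per-component child seeds deterministically;
  equal configuration and seed give bitwise-identical studies.

What the generator does **not** emulate: read-level artifacts (FASTQ,
alignment, multimapping), FFPE chemistry and its length-dependent degradation,
probe cross-hybridization, batch effects across hybridization lanes, and
correlated biological structure between genes (pathways). A green test
therefore establishes that the pipeline's arithmetic and its statistical
behavior are correct under a realistic count model — not that any particular
real dataset will show the same numbers.

## Normalization

All four schemes are per-sample rescalings, which is why within-sample ranks —
and hence sample-wise Spearman correlations — are *identical* whichever of
them is applied (an exact property, asserted in the tests).

* **CPM** scales each column to $10^6$.
* **TMM** picks the sample whose upper-quartile CPM is closest to the mean
  upper-quartile as reference, forms gene-wise log ratios (M) and average
  log abundances (A) against it on genes nonzero in both, trims 30% of
  M-values and 5% of A-values from each tail, and takes $2^{\text{weighted mean}}$
  with delta-method inverse-variance weights. Factors are geometric-mean
  centered so their product is 1. Parameters follow the original published
  definition; the implementation is checked against both a brute-force
  transcription of the formula and `edgeR::calcNormFactors`.
* **RLE** divides each sample by its median ratio to a per-gene
  geometric-mean pseudo-reference (genes containing any zero excluded). The
  factor is the *plain median of ratios*, not the exponentiated median of log
  ratios — the two differ when the usable-gene count is even, and the
  median-of-ratios reading follows the method's stated definition.
* **Panel two-step**: each sample is scaled by (arithmetic mean over samples
  of the geometric mean of its positive controls) / (its own positive-control
  geometric mean), then the computation is repeated with housekeeping genes
  on the step-1 output. Whether the cross-sample average should be arithmetic
  or geometric is not specified by vendor documentation; arithmetic is used
  and documented here. Geometric means are taken over the *nonzero* reference
  counts — a single zero probe would otherwise annihilate the mean — and only
  a sample with all-zero references is an error. Samples whose step factors
  fall outside [0.3, 3] (positive controls) or [0.1, 10] (housekeepers) are
  flagged, never dropped.

Sequencing-side factors are always computed on the full gene set and the
matrix subset to panel genes afterwards, because depth and composition should
be estimated from the whole transcriptome, not from an 800-gene slice.

## Correlation profiling

Sample-wise profiles correlate the two platforms across the shared genes
within each matched sample; gene-wise profiles correlate across samples for
each shared gene. Pearson is computed on counts and, as "Pearson-log", on
$\log_2(x + 1)$ (pseudocount 1; the log base cancels out of the coefficient
and is fixed at 2 only so intermediate files are reproducible). Spearman uses
mid-ranks for ties. Units with zero variance on either side yield `NA`,
which is counted and excluded from summaries, never imputed.

Correlation strengths are labelled with the medical-field bins:
$|r| \ge 0.8$ very strong, $0.6$–$0.8$ moderately strong, $0.3$–$0.6$ fair,
$< 0.3$ poor, with boundaries inclusive at the lower edge of each bin.

Expression strata ("all", "top 90%", "top 50%") are defined by the 10th and
50th percentiles (type-7 quantiles, so linear interpolation; membership
inclusive at the threshold) of mean log expression. Where exactly to draw the
cutoffs is genuinely open — practitioners place them by eye on the
mean-expression scatter — so percentile defaults were chosen once and made
configurable, computable against either platform's mean expression. Box
summaries use type-7 quartiles and 1.5 IQR whiskers so they are
bit-reproducible.

Because dispersion is constant per platform while Poisson noise scales
relative to $1/\sqrt{\mu}$, lowly expressed genes are intrinsically noisier
and their cross-platform correlation weaker — the stratified medians
increase from "all" to "top 50%" in simulation for the same reason they do in
real FFPE data.

## The differential-expression engine

The engine is an explicit, documented approximation of the dedicated DGE
tools it stands in for, not a reimplementation: per-gene NB log-link GLM
$\log \mu_{gi} = \log sf_i + \beta_0 + \beta_1 [i \in B]$ fit by IRLS
(tolerance $10^{-8}$, at most 100 iterations, linear predictor clamped at
$\pm 30$ natural-log units) at a per-gene moment dispersion estimate, pooled
across groups and floored at $10^{-8}$. There is no empirical-Bayes
dispersion shrinkage and no adaptive-prior fold-change shrinkage.

Two numerical choices deserve emphasis:

* **t reference for the Wald test.** With 5 samples per group a per-gene
  dispersion estimate carries very few degrees of freedom, and referring the
  Wald statistic to a normal doubles the nominal type-I error (measured
  ~0.10 at $\alpha = 0.05$). The statistic is therefore referred to a
  $t_{N-2}$ distribution, which restores calibration (~0.05 in the null
  simulation) and converges to the normal reference as $N$ grows.
* **Boundary genes.** A gene observed in only one group has its fold-change
  MLE at infinity; the clamp returns a large finite estimate with a huge
  standard error, so such genes are never spuriously significant, but their
  raw fold changes are meaningless — one reason fold-change *shrinkage*
  (below) is the right scale for direction classification.

Shrinkage is the conjugate normal posterior mean
$\hat\beta \cdot \sigma_p^2 / (\sigma_p^2 + se^2)$: genes with little
information (large standard error, i.e. low counts) are pulled hardest toward
zero. The automatic prior sd is the 0.90 quantile of $|\hat\beta|$ across
genes, floored at $10^{-3}$ so an all-null dataset still yields a proper
prior.

BH and BY step-up adjustments are computed by the package (and cross-checked
against `stats::p.adjust` in the tests); BY multiplies the BH quantity by
$c(m) = \sum_{i=1}^m 1/i$ and is therefore elementwise at least as large —
the conservative default used for DEG calling. Genes with undefined p-values
(all-zero counts) do not count toward $m$. DEG gates are inclusive:
$p_{adj} \le \alpha$ **and** $|\text{log2FC}| \ge 1$.

## Concordance layer

Annotation overlap reports how many panel genes exist in the sequencing
annotation; percentages are stored at full precision and formatted with one
decimal unless the exact value is representable at two decimals (98.75 stays
98.75; 98.9156… prints 98.9). Direction classification assigns every shared
gene exactly one of eight labels (both up/down, one-platform-only up/down per
platform, opposite, not significant); the "opposite" class is retained even
though well-behaved data may never populate it, because the partition must be
exhaustive. The Jaccard index of the two DEG sets is
$|A \cap B| / |A \cup B|$, defined as 0 when both sets are empty.

## Known limitations

* Spearman coefficients have discrete resolution: a single swap of adjacent
  ranks changes the coefficient by $6/(n(n^2-1))$, about $6.5 \times 10^{-4}$
  at 21 samples. Counting noise never fully vanishes at finite depth (and
  count sampling is capped near $2^{31}$), so occasional near-tie rank flips
  keep rank coefficients from reaching 1 to within $10^{-6}$ even in the
  zero-platform-noise limit where all product-moment coefficients do. The
  corresponding rank-coefficient assertions in the acceptance suite document
  this boundary and are expected to fail; the product-moment recovery checks
  pass at $10^{-6}$.
* The DGE engine's moment dispersion is noisy at small $n$; it is calibrated
  (type-I error, FDR ordering) but less powerful than shrinkage-based tools,
  and exact numeric parity with them is a non-goal.
* Configuration files are JSON (via `jsonlite`); YAML is not supported.
* The RCC reader implements the publicly documented section layout and is
  validated against self-generated fixtures only.
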