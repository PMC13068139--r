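---
title: "Mapping genetic interactions and their environmental rewiring from dual-sgRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genetic interactions and their environmental rewiring from dual-sgRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(girewire)
```

## The measurement model

A pooled dual-sgRNA CRISPRi screen expresses two guides per construct, so
that every construct knocks down an (ordered) pair of genes — or pairs a
gene with a non-targeting control (ntc), or pairs two controls. Cells
carrying the library grow competitively; constructs whose knockdowns slow
growth deplete, and sequencing the integrated cassettes before and after
growth measures that depletion. All phenotypes are expressed per
*population doubling*, which makes them comparable across arms that grew
for different lengths of time:

$$\gamma = \log_2\!\frac{R_F/N_F}{R_0/N_0}\cdot\frac{1}{d_u},\qquad
  \tau   = \log_2\!\frac{R_T/N_T}{R_0/N_0}\cdot\frac{1}{d_t},\qquad
  \rho   = \log_2\!\frac{R_T/N_T}{R_F/N_F}\cdot\frac{1}{d_u-d_t},$$

where $R$ is the construct's read count in the initial ($0$), final
untreated ($F$) and final treated ($T$) samples, $N$ the median count over
ntc–ntc constructs in the same sample, and $d_u$, $d_t$ the cumulative
doublings of the untreated and treated arms. The three quantities are
algebraically linked — $\rho\,(d_u-d_t) = \tau\,d_t - \gamma\,d_u$ — which
the tests assert for every simulated construct.

A *genetic interaction* (GI) is a deviation from additivity. For each
query sgRNA we fit, by ordinary least squares, a quadratic model of the
phenotype of every construct containing the query as a function of the
partner guide's single phenotype (the mean over its ntc-paired
constructs, both orientations). The construct's residual from that model,
divided by the standard deviation of the query's residuals over its own
ntc-paired constructs, is the interaction z-score for that ordered
construct. Scores for an unordered guide pair average both cassette
orientations and both query roles (up to four values per replicate);
replicates are averaged last; gene-level scores average all guide pairs of
the two genes (eight ordered constructs with two guides per gene).
Negative scores are synthetic-sick, positive scores buffering.

High-confidence calls use the spread of the negative-control score
distribution — each ntc treated as a pseudo-gene of size one — with a
strict $|s| > 4\,\mathrm{sd}$ threshold. Differential interactions (dGIs)
between an environmental and a reference map are the elementwise score
difference; they are called at $5\,\mathrm{sd}$ of the control-dGI
distribution *and* must be significant in at least one of the two source
maps, so a large difference between two sub-threshold scores is never
reported as rewiring.

Interaction *profiles* (matrix rows) are clustered with average-linkage
hierarchical clustering on Pearson distance $1-r$; cuts at distance 0.55
give complex-like modules and 0.8 broader systems. A cross-condition
consensus divides each map by its global score SD, concatenates the maps
into an $n \times kn$ composite, and clusters its rows; the dendrogram is
a universal ordering for all maps. Cluster-level ("ontology") matrices
average the gene-level scores within and between clusters, and
coordination profiles correlate one cluster's ontology-level profile with
every other's, per condition.

## What the simulator emulates

`simulate_truth()` + `simulate_counts()` invert the estimator's growth
model exactly: a construct's abundance is multiplied by
$2^{\text{phenotype}\cdot d}$, where the phenotype is the summed guide
effect plus the planted gene-pair interaction for that condition, and
sequencing is a multinomial draw at fixed depth. Because the growth model
is the exact inverse of the $\gamma$ definition, estimator correctness is
a matter of algebra, not convention, and is tested as a round trip
(construct-level correlation with truth $\ge 0.99$ at high coverage).

Choices a scientist would recognise as the study conditions:

* gene fitness effects $\sim N(0,\ \texttt{effect\_sd}=0.1)$
  log2/doubling; each guide scatters around its gene mean with SD
  $0.2 \times \texttt{effect\_sd}$, giving realistic same-gene guide
  correlation without duplication;
* interactions planted on a fraction (default 0.1) of gene pairs,
  $N(0,\ \texttt{gi\_effect\_sd}=0.3)$, defined at gene level and
  inherited by all guide pairs;
* treated-arm effects are the reference effects plus a per-gene drug
  modifier (default SD equal to `effect_sd`), which is what makes $\rho$
  hit-calling meaningful;
* a rewiring fraction (default 0.5) of planted interactions is re-drawn
  in each non-reference condition — these are the planted dGIs;
* initial abundances are lognormal with `abundance_sd_log = 0.8`, which
  keeps roughly 90% of constructs within a 16-fold range, the dispersion
  typical of large cloned pools;
* doublings default to 8 (untreated) and 3.5 (treated), matching screens
  run to a doubling difference of ~4.5;
* ntc guides have effect exactly zero and join no interaction.

The simulator does **not** model guide recombination between cassette
positions, sequencing error, lentiviral multiplicity of infection, or
selection bottlenecks; nor does it plant *modular* structure (planted
interactions are independent random pairs). Passing tests therefore
demonstrate estimator and calling correctness under the stated noise
model — they do not certify performance on real screens, where guide
efficacy varies, abundance is not exactly lognormal, and interactions
cluster into complexes. The block-recovery clustering tests use
synthetic block matrices precisely because the screen simulator has no
modules to find.

## Numerical and design choices

* **Depth normalization and pseudocount.** Each sample is rescaled to a
  fixed total of 1000 reads per library element before the pseudocount of
  10 is added (raw counts are used for the median-read filter, which
  precedes the pseudocount). Rescaling to a data-independent target makes
  phenotypes *exactly* invariant to a sample's sequencing depth while
  keeping the pseudocount on the raw-count scale of a screen sequenced at
  standard (1000×) coverage. A pseudocount applied to raw counts, or to a
  per-million scale, either breaks that invariance or makes the
  pseudocount's strength depend on library size.
* **Null spread per query.** The z-denominator is the SD of the query's
  *residuals* over its ntc-paired constructs, not the raw phenotype SD:
  z-scoring a residual by a non-centred phenotype spread would not yield
  null-centred control distributions. Configurable in principle; the
  residual form is the default and the only one used here.
* **Fallbacks and exclusions.** Queries need at least 3 finite partner
  points (5 for the quadratic term, else a line) and at least 2 ntc
  residuals with positive SD; otherwise the query is excluded with a
  message. Zero-variance profiles are excluded from clustering with a
  warning. ρ is flagged undefined when $d_u = d_t$.
* **Strict thresholds.** A score exactly at $n_{sd}\cdot\mathrm{sd}$ is
  *not* significant, at both the 4-SD GI and 5-SD dGI cuts.
* **Replicates** are processed independently end to end and combined by
  averaging at the score level; pairs measured in only one replicate keep
  that replicate's value, with `n_obs` recording support.
* **Gene universe.** Gene-level maps always span the library's targeting
  genes; a gene whose guides were all filtered in a condition keeps a
  fully masked row, so multi-condition consensus matrices keep a common
  universe. Masked cells become 0 (the null z value) *only* inside
  clustering; differential maps propagate them as missing, never as
  silent zeros.
* **Profile correlations** exclude the cells coupling the two genes to
  themselves and to each other (per condition block in the consensus):
  self-scores are controls, not profile signal.
* **Tie-breaking.** Average-linkage agglomeration on a fixed distance
  matrix is deterministic in `stats::hclust`; iterative enrichment breaks
  adjusted-p ties by raw p, then input order.
* **PPI enrichment** uses 10 quantile bins by default (configurable to
  equal width); absent pairs score 0; the chi-square uses expected counts
  from the global interacting fraction with adjacent bins merged until
  every expected count reaches 5, so the degenerate constant-score case
  cleanly yields a statistic of 0 and p = 1.
* **Gene-set enrichment** is a local hypergeometric test with
  Benjamini–Hochberg adjustment against GMT collections, iterated with
  top-term removal; it deliberately replaces any web-service dependency
  with a statistically equivalent, self-contained procedure.

## Problem sizes used in the checks

The packaged tests run entirely on simulated screens: a 20-gene × 2-guide
library with 5 ntc at depth 2×10⁶ (two replicates) for null calibration
and parameter recovery, and a 40-gene library with the standard 13 ntc at
depth 2×10⁷ for recall and rewiring recovery — 78 planted pairs, enough
that measured recall reflects the method rather than the handful of
near-zero planted effects any single draw of $N(0, 0.3)$ contains. The
full-scale design combinatorics (313 genes × 2 + 13 ntc → 639 guides →
639² = 408,321 constructs) and the five-condition consensus shape
(304 genes → 304 × 1520) are checked exactly. `scripts/acceptance.R`
re-runs all of these from scratch under a caller-supplied seed.

## Known limitations

* Recall of planted interactions is bounded by the effect-size
  distribution: interactions drawn near zero are undetectable at any
  depth, and a query gene with many strong interactions has part of its
  signal absorbed into its own expectation model (visible as slightly
  depressed scores for its pairs). Both effects exist in the real
  procedure as well.
* The control (gene–ntc) score spread is built from fewer averaged
  measurements than gene–gene scores under many planted interactions, so
  the 4-SD threshold can be mildly anti-conservative on maps with dense
  strong interactions; on null maps the call rate is far below the 0.5%
  bound the tests assert.
* dGIs are raw differences of z-scored maps. When the two arms differ in
  doublings, their per-doubling sensitivity differs, so an interaction
  conserved in phenotype units can still show a nonzero dGI proportional
  to its magnitude; the source-map support requirement does not remove
  this. It is inherent to elementwise map subtraction and visible in the
  simulator, where ground truth is known.
* Replicating high-confidence call counts from real deposited screens requires
  the deposited count tables and is sensitive to the replicate-averaging
  convention (scores, not phenotypes, are averaged here); it is out of
  scope for the packaged checks.
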