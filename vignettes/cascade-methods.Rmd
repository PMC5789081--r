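---
title: "Methods: knowledge-guided temporal clustering and cascade reconstruction"
author: "txcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-guided temporal clustering and cascade reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcascade)
```

This vignette is the package's own account of its statistical machinery: the
models, the tunable parameters and their defaults, the numerical choices made
where the design was genuinely open, what the synthetic-data generator does
and does not emulate, and the known limitations.

## The analysis problem

A time-resolved transcriptomic experiment measures expression at a few
timepoints (here 2, 4, 8 and 24 h) under one or more perturbations with
time-matched controls and a small number of replicates (typically two). The
analysis goal is three-layered: (1) which genes respond, and when; (2) which
genes share a temporal response profile; and (3) which transcription factors
(TFs) drive each profile, and in what order — a *transcriptional cascade*, in
which early-responding TFs induce later waves of transcription, including
other TFs. Layer (3) is only identifiable with prior knowledge; the package
uses a table of experimentally validated TF→target-gene (TG) interactions
with an integer evidence rank (tier 1 strongest), filtered by default to
ranks 1–2.

## Differential expression

Each treatment condition is contrasted against the time-matched control,
separately per timepoint, with a two-sample moderated t-test.

**Model.** Per gene, the pooled within-group variance $s^2$ (on
$d = n_A + n_B - 2$ degrees of freedom) is assumed to follow a scaled
chi-squared sampling distribution around a true gene variance, which itself
follows a scaled inverse chi-squared prior with $d_0$ degrees of freedom and
location $s_0^2$. The posterior variance
$\tilde{s}^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ replaces $s^2$ in the ordinary
pooled t-statistic, which is then referred to a t distribution on $d + d_0$
degrees of freedom ($d_0 = 0$ recovers the ordinary t; $d_0 = \infty$ gives a
z-test at the prior variance).

**Prior estimation.** $(d_0, s_0^2)$ are estimated by moment matching on
$z = \log s^2$: under the model, $\operatorname{Var}(z) =
\psi'(d/2) + \psi'(d_0/2)$, so the excess of the empirical variance of $z$
over the sampling floor $\psi'(d/2)$ determines $d_0$ through a trigamma
inversion (Newton iteration), and the mean of $z$ determines $s_0^2$ after
removing the chi-squared log-scale bias $\psi(d/2) - \log(d/2)$. Two
degenerate regimes need care:

* **Literally constant variances** (empirical variance of $z$ ≈ 0): the
  variances carry no sampling dispersion at all, so the prior is a point mass
  at the common value — $s_0^2$ is the geometric mean (= the common value).
* **Dispersion at or below the sampling floor** (possible by chance even when
  the true prior is a point mass): $d_0 = \infty$ with the *bias-corrected*
  location $s_0^2 = \exp(\overline{z} - \psi(d/2) + \log(d/2))$. Using the
  raw geometric mean here would understate $s_0^2$ by
  $e^{\psi(d/2)-\log(d/2)}$ (44% at $d = 2$), inflate every t-statistic, and
  break false-discovery control — this was observed directly in simulation
  and is why the two regimes are distinguished.

One prior is fitted per contrast (per timepoint), keeping contrasts
independent and matching the per-timepoint DE definition; estimation requires
at least 10 genes.

**Thresholds.** A gene is DE at a timepoint when |log₂FC| > 0.5 **and**
BH-adjusted p < 0.05 (`de_config()`; both thresholds must be passed, so a
tiny-but-significant fold change is not DE). "Early" is DE at any of 2/4/8 h,
"late" at 24 h; the two sets may overlap. With two replicates per group,
moderation can be mildly anti-conservative; in planted-truth simulations the
empirical FDR at nominal 0.05 stays near 0.04 (tolerance 0.10 in the tests).

## Cross-condition comparisons

Differences in DE-gene *frequency* between conditions (or timepoints) are
tested with the chi-squared test with Yates's continuity correction,
$\chi^2 = N(\max(|ad-bc| - N/2,\, 0))^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ on
1 df; the correction is clamped at zero, so exactly equal proportions give
$\chi^2 = 0$, p = 1. Overlap of DE sets with curated signatures is scored by
the one-sided hypergeometric test at a fixed symbol universe (default 41220
approved symbols) with the percentage reported relative to the signature;
signature collections are size-filtered (at least 30 genes, the collection's
`min_size`).

## Temporal profiles and clustering

The DE union of the clustered condition is summarised as a gene × time matrix
of log₂ fold changes, z-standardised per gene (mean 0, SD 1 across
timepoints; rows constant over time become all-zero). Standardising removes
magnitude so clustering responds to *shape*. Clustering is agglomerative with
Euclidean distance and Ward's squared-distance linkage (`ward.D2`), cut to
exactly K groups — hierarchical clustering gives singular, deterministic
memberships; k-means and fuzzy c-means are provided for score comparison and
are re-seeded deterministically per K.

**Choosing K.** Each candidate partition is scored by how well known TF
target sets co-cluster: for every cluster and every TF with at least one
target among the clustered genes, a one-sided Fisher test of the target set
in the cluster (background = the clustered genes, since the partition only
covers DE genes). Two raw scores are exposed:

* `"neglogp"` (default): mean over clusters of $-\log_{10}(\min p)$, counting
  clusters whose best TF is not below `alpha` as 0.
* `"fraction"`: the fraction of clusters containing at least one enriched TF
  set (p < `alpha`).

The fraction score is piecewise-constant in K on well-structured data —
merging two fully-enriched clusters, or splitting one, typically leaves every
cluster enriched, so whole ranges of K tie at 1.0 and the score cannot locate
the true K. The magnitude-based score peaks at the true K (merging dilutes
the draw, splitting halves the overlap, and both weaken $\min p$), which is
why it is the default. Scores are normalised by their maximum so the chosen
configuration scores exactly 1.0; ties break to the smallest K. If no
candidate shows any knowledge-base signal the selection falls back, with a
warning, to the $\sqrt{n/2}$ heuristic.

## TF enrichment and the cascade

Per-cluster TF enrichment uses the same Fisher test and flags TFs at
**uncorrected** p < 0.05; pathway over-representation on GMT collections is
BH-corrected at FDR < 0.05. The asymmetry is deliberate and preserved from
the analysis convention this pipeline codifies: the TF threshold feeds a
rule-based graph construction (where downstream filtering provides further
control), while pathway lists are reported directly. The enrichment
background defaults to the clustered genes; an array-wide background can be
supplied.

The cascade graph is assembled from four rules:

1. a TF enriched in a cluster is **upstream** of it;
2. every DE TF assigned to a cluster gets a **membership** edge;
3. a TF B **connects** clusters I → II when it is DE in cluster I, a known
   target of a TF upstream of cluster I, and enriched in cluster II (the
   supporting TF→TF edges are emitted as **regulatory** edges);
4. because a cascade requires TFs regulating TFs, an enriched TF enters the
   graph only if it participates in a TF–TF relationship.

Rule 4's scope was genuinely open. The strict outbound reading — at least one
of the TF's targets is itself a TF, DE in a cluster where the TF is enriched
— excludes exactly the connector situation of rule 3 (a terminal-wave TF
whose targets are not TFs, but which is itself the regulated TF). The filter
therefore also admits an *inbound* route, iterated to a fixpoint: an enriched
TF that is DE in a cluster and a knowledge-base target of a TF already
upstream of that cluster. A `"permissive"` mode (any TF target qualifies) and
`"none"` are available. Connectors with I = II are annotated `self = TRUE`
and can be excluded. Enriched TFs that are not themselves clustered are kept
as upstream-only nodes — regulation of their activity is presumably
post-transcriptional, which expression data cannot see.

Clusters are compared against external single-timepoint contrasts with the
mean-rank gene-set test: genes are ranked by the external log₂ fold change
(average ranks for ties) and the set's mean rank is referred to its normal
approximation, $z = (\bar{r}_{set} - (N{+}1)/2) / \sqrt{(N-m)(N{+}1)/(12m)}$.
Both one-sided p-values are reported and the direction is the smaller one; a
`"mixed"` alternative ranks by |statistic|. The approximation's null
uniformity is verified against permutation in the tests. Clusters with fewer
than 5 externally covered genes are flagged untested, and at least 80% of
clustered genes must be covered overall.

The anti-oxidant reversal analysis counts model-vs-control DE genes whose
model+AO-vs-model contrast is DE **with opposite sign at the same timepoint**
— full significance is required by default (sign-only opposition is a flag)
because "reversed" should mean the same evidentiary standard as "changed".
Note that the two contrasts share the model samples, so a rare extreme
replicate can fake a reversal; simulations put this contamination below 10%
of detected reversals at the default noise level. The accompanying Jaccard
index compares the DE sets with and without AO, both against control, and
therefore needs the model+AO-vs-control table (optional argument; `NA`
otherwise).

## The synthetic-data generator

`sim_config()` fixes the study design the generator emulates: 2 replicates ×
timepoints {2, 4, 8, 24} h × conditions {control, drugA, drugB, both} with
effect multipliers {0, 0.3, 0.3, 1}, concentrating the response in the
combined condition. Planted genes fall into `k_true` clusters of
`cluster_size` genes; each cluster follows one of eight non-constant profile
templates scaled by `effect_size` (default 2 log₂ units) on top of a
gene-specific baseline (uniform 6–10 log₂ intensity) and Gaussian noise
(`noise_sd`, default 0.25 log₂ units; a heavier-tailed Student-t option
exists for robustness checks). A strictly positive noise floor is enforced —
zero noise degenerates the t-statistics. Defaults (5000 genes, 50 TFs,
K = 6, cluster size 40) let the full pipeline run in seconds on one CPU.

The knowledge base plants a *chained* cascade: driver TF $D_c$'s rank-1
target set is exactly cluster $c$, and for $c \ge 2$, $D_c$ is itself a
member gene of cluster $c-1$ — so $D_c$ is DE with cluster $c-1$'s profile
and a target of $D_{c-1}$, making $D_2 \dots D_K$ the planted connectors.
$D_1$ is a non-DE background gene (an upstream-only regulator, as a
post-translationally activated TF would appear), one member of the last
cluster is additionally annotated as a TF (so the terminal driver also
regulates a TF), and the remaining TFs are decoys with random target sets at
mixed evidence ranks 1–3. Planted upstream TFs are, by construction,
genuinely Fisher-enriched in their clusters at the generated sizes.

**What passing tests do and do not show.** The generator produces
independent Gaussian noise, block-exact target sets, equal cluster sizes and
a single effect size — real microarray data have correlated genes, batch
effects, incomplete and erroneous TF annotations, heavy-tailed intensities
and a continuum of effect sizes. Recovery of the planted cascade therefore
validates the *correctness of the machinery* (the statistics, the K
selection, the placement rules), not the expected sensitivity on real data,
where annotation coverage is usually the binding constraint.

## Numerical choices and problem sizes

* Ties in ranks: average ranks; ties in K selection: smallest K (and the
  first listed method).
* Yates correction clamped at zero; zero-margin 2×2 tables are errors from
  `yates_chi_squared()` and reported as `NA` rows by `condition_overlap()`.
* Zero per-gene variances are excluded from prior estimation (with a
  warning); a zero residual variance with a non-zero fold change is an error
  rather than an infinite statistic.
* Probe-to-gene collapsing defaults to the per-sample median across a gene's
  probes, preserving sample-wise temporal structure, which downstream
  clustering requires. The literal single-representative-probe alternative
  (the probe whose across-sample average is the median of those averages) is
  available as `method = "median_average_probe"`.
* Gene identifiers are case-preserved strings matched exactly.
* Test and acceptance runs use 600–5000 genes, 4–50 TFs, K 2–6 planted
  clusters and 10–20 seeds per property; the complete suite runs in well
  under a minute on one CPU.

## Limitations

* Contrasts are two-group per timepoint; no spline/time-course models,
  covariates or interaction contrasts.
* The cascade encodes direction of regulation but not sign
  (activation/repression), and inherits any bias of the knowledge base.
* The enrichment score's exact form is a design choice (documented above);
  reported scores are comparable within one run, not across knowledge bases.
* Normalisation (e.g. RMA) is out of scope: expression input is assumed
  already log₂-scale and normalised.
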