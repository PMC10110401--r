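---
title: "Methods: quantifying RBP target displacement from paired RNA-seq and RIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying RBP target displacement from paired RNA-seq and RIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripcouple)
```

## The experimental design being modeled

An RBP-displacement study profiles three conditions — `control`, `stimulus`
(an inflammatory trigger such as LPS) and `stimulus_drug` (the trigger plus
an RBP inhibitor) — in two sequencing assays: RNA-seq of total input RNA
and RIP-seq of RNA co-immunoprecipitated with the RBP (IP libraries, with
IgG mock IPs retained for the qPCR validation path). Each condition × assay
cell is sequenced in quadruplicate. The scientific question is not whether
the drug blocks the transcriptional response (it largely does not) but
whether it *uncouples* transcript abundance from RBP binding: stimulated
cells show a strong positive correlation between per-gene expression
changes and binding changes, and a displacing drug lowers that correlation
for the genes it strips off the protein.

## Differential testing

Counts are normalized with median-of-ratios size factors, rescaled to
geometric mean 1 so that factors are interpretable as relative depths.
The per-gene test is a negative-binomial Wald contrast on group means of
normalized counts, with `Var = mu + alpha * mu^2`:

* `log2fc = log2((m_B + c) / (m_A + c))` with pseudocount `c = 0.5`
  (configurable), which keeps fold changes finite when one group is all
  zero; a gene with zero counts everywhere is reported as
  `log2fc = 0, p = 1` rather than an error.
* The dispersion `alpha_g` is first estimated per gene by method of moments
  pooled across the two groups, then — by default — replaced by the fitted
  mean–dispersion trend `alpha(mu) = a0 + a1 / mu` across all genes
  (`dispersion = "trend"`). The reason is statistical, not cosmetic: with
  four replicates per group the per-gene moment estimate has roughly six
  degrees of freedom, and plugging it into a Wald statistic referred to the
  normal distribution inflates the null rejection rate to about 0.10 at a
  nominal 0.05. The trend borrows strength across thousands of genes, and
  the same null simulation then rejects at about 0.055. The trend is fitted
  by least squares on the untransformed moment estimates — including
  negative ones, which keeps the fit unbiased around the true dispersion —
  and floored at `alpha_min = 1e-8`. `dispersion = "genewise"` restores the
  raw per-gene estimates for users who prefer transparency over
  calibration; the trade-off above is then theirs.
* Standard errors come from the delta method under the NB variance with the
  fitted dispersion; p-values use the normal reference (a documented
  large-sample approximation at n = 4) and are BH-adjusted.
* Classification is strict: `up` requires `padj < 0.05` **and**
  `log2fc > 1`; boundary values are `nd`.

The transform used for PCA, clustering and scores is `log2(normalized + 1)`
— a monotone, variance-flattening map whose tag travels with the matrix so
outputs declare what they were computed on. Clustering uses average linkage
on `1 - Pearson r`; PCA is on gene-centered samples.

## Coupling scores and why they are plain contrasts

Each gene gets one score per assay and contrast: the difference of
condition means of the transformed matrix (treated minus control), i.e. a
moderated log2 fold change in transformed space. An option standardizes the
scores across genes (the "z-score" presentation common on scatter axes);
Pearson correlations are invariant to that choice, so the default keeps the
raw contrast, whose sign also matches the true induction direction
gene-by-gene.

A tempting alternative — z-scoring each gene's row across samples and
differencing condition means of those z-scores — turns out to be unusable
for this analysis: row z-scores are scale-free, so every strongly induced
gene collapses to the same saturated pattern (the score tends to a constant
that no longer depends on effect size). Across a set of strong responders
the between-gene variance then consists almost entirely of replicate noise,
and the "coupling correlation" measures nothing. This is easy to verify
with the synthetic generator, where the truth is known; the package
therefore defines the score as the plain condition contrast and records the
definition in the output metadata.

The coupling correlation is the Pearson r (with the t-reference p of
`cor.test`) between the RNA and RIP scores over a filtered gene set. The
cascade takes five differential tables and intersects:

* `S_lps`: RNA `up` (padj < 0.05, log2fc > 1) ∩ RIP enriched
  (padj < 0.05, log2fc > 3) for stimulus vs control. The RIP threshold is
  deliberately higher: IP libraries inherit the transcriptional induction
  *and* add binding enrichment, so 8-fold is the scale at which binding,
  not abundance alone, drives membership.
* `S_drug`: the same for stimulus + drug vs control.
* `S_common = S_lps ∩ S_drug`, and
  `S_displaced ⊆ S_common`: genes whose IP signal significantly decreases
  in drug vs stimulus (padj < 0.05, log2fc < 0 — no magnitude cutoff, since
  any significant loss of binding within an induced, still-enriched gene is
  displacement).

RIP contrasts are computed across conditions on IP libraries, matching how
enrichment fold changes are usually reported for RIP-seq; an IP-vs-input
interaction contrast can be assembled from the same primitives but is not
the default. Whether the published correlation in such studies is computed
on per-condition means or replicate pairs is typically not stated; one
value per gene per comparison (the condition-mean contrast) is the
definition used here, consistently for correlations, scatters and density
surfaces.

## The density-difference surface

The two score scatters (stimulus set and drug set) are summarized by
Gaussian product-kernel densities on one shared 64 × 64 grid: Silverman
bandwidths per axis from the pooled points, window = pooled 1%–99%
quantiles padded by 3 bandwidths, each density renormalized to integrate to
1 by the trapezoid rule, and the difference taken nodewise. The regular
grid is triangulated (two triangles per cell) purely for 3-D rendering;
all numerics use the grid itself. Consequences worth knowing: identical
inputs give an exactly zero surface, swapping the arguments negates it
exactly, and the KDE of a 5000-point standard-normal sample at the mode is
within a few percent of the analytic `1/(2*pi)` (small negative bias of
order `h^2`, as expected).

## ARE scanning and UTR statistics

Sequences are normalized to uppercase RNA on load (T → U; a record mixing T
and U is rejected as ambiguous). Motif classes default to the canonical
ARE tiers — `AUUUA`, `UUAUUUAUU`, `WUAUUUAUW`, `WWUAUUUAUWW`,
`WWWUAUUUAUWWW` — scanned on the given strand with *overlapping* matches
counted (ARE clusters overlap by construction; a non-overlapping count can
be derived from the returned positions). `N` never matches. The per-gene
`total` is the pentamer count, the shortest and therefore most permissive
tier; which tier a database reports is configurable because conventions
differ.

Group comparisons (up / down / nd genes) use the Wilcoxon rank-sum test:
exact by enumeration for tie-free samples with 12 or fewer values in total,
normal approximation with tie and continuity correction otherwise. The
"below-average ARE" flag is a strict comparison of a gene's total count
against the arithmetic mean over the whole profiled universe; the universe
choice (all profiled genes vs an expressed subset) is an argument, since a
results sentence like "k of n genes had fewer AREs than average" rarely
defines it.

## Assay calculators

Fold enrichment is `2^-dCt` with `dCt = mean(Ct_IP) - mean(Ct_IgG)`. Ct
values are log2-scale quantities, so the "ratio" of IP to IgG signal is a
*difference* of cycle thresholds; the implementation uses the difference,
which gives enrichment > 1 when the IP amplifies earlier, and propagates
replicate SDs by the delta method. Relative expression is the standard
`2^-ddCt` with means of Cts per condition; both calculators are exactly
invariant to a common Ct offset. The dose-response fit is least squares on
`y = bottom + (top - bottom) / (1 + (x/IC50)^h)` with `h = 1` in one-site
mode (the slope is freed in `four_param` mode, provided because published
"one-site" fits do not always say which was used), multi-start over a
log-spaced IC50 grid spanning the tested concentrations, best-RSS
convergent fit returned, and a flag when the fitted IC50 falls outside the
tested span.

## The synthetic generator

Defaults (all overridable in `sim_config()`): 2000 genes, 4 replicates,
20% responsive genes with log2 induction `beta ~ N(2.5, 1.5^2)`, binding
probability 0.8 for responsive and 0.3 for background genes, binding effect
`b ~ N(3.5, 0.8^2)` with `cor(beta, b) = 0.85` among responsive∩bound genes
(bivariate-normal draw — the simplest mechanism with a controllable target
correlation), 25% of bound responsive genes displaced with the binding
effect multiplied by 0.25 under drug, a small extra drug effect on
transcription (`N(0, 0.25^2)`), lognormal base means (median 100 — the
regime of a filtered count matrix), lognormal NB dispersions around 0.05,
relative depths uniform in 0.7–1.3, IgG at 2% of input.

Two modeling choices deserve emphasis. First, binding probability is higher
among responsive genes: stimulus-induced inflammatory transcripts are
predominantly ARE-containing RBP targets, which is the premise of this kind
of study; without it the filtered sets fill up with induced-but-unbound
genes that sit on the abundance diagonal and dilute the coupling. Second,
the binding enrichment of IP libraries applies in the *stimulated*
conditions (attenuated by the displacement factor for displaced genes under
drug). If instead a constant enrichment were applied in every condition it
would cancel from every condition contrast — RIP fold changes would equal
RNA fold changes in expectation and the coupling analysis would degenerate
to a noise artifact, contradicting both the distinct RNA/RIP thresholds and
the binding induction such experiments report.

UTRs are lognormal in length (median ≈ 400 nt, bound genes shifted +0.7 in
log, floored at `5k + 10` for `k` planted sites), with `Poisson(5)` planted
non-overlapping `AUUUA` pentamers for bound genes vs `Poisson(1)` for
unbound, in a GC-weighted background (A/U at 12% each) so spurious motifs
are rare but possible — recovery tests therefore compare scans against a
window oracle, not against the planted count alone.

Draws are ordered truth → input counts (control, stimulus, drug) → IP
counts (same order) → IgG. Hence experiments that differ only in the
displaced fraction share identical control/stimulus draws at the same seed
(common random numbers), which makes "the stimulus-condition coupling is
flat across displacement levels" an exact statement rather than a noisy
comparison, and sharpens paired drug-vs-stimulus contrasts.

What the generator does **not** emulate: compositional (sequencing-depth
competition) effects on IP libraries, GC/length biases, outlier samples,
batch structure, transcript-isoform ambiguity, correlated gene modules, or
competition between RBPs for shared targets. Passing recovery tests on this
generator therefore demonstrates the correctness and calibration of the
computations, not robustness to every artifact of real libraries.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen to
finish in minutes while keeping Monte-Carlo margins comfortable: 2000-gene
experiments (five seeds per condition where medians are compared), a
5000-gene null for calibration, 1000 random sequences against the scanner
oracle, 50 noisy dose-response refits. With the displaced fraction at its
default 0.25 the coupling correlation typically drops from about 0.8 to
about 0.6 — the same uncoupling signature, at 2000 genes, that motivates
the method. All randomness flows from a single user-supplied seed; a run's
outputs carry a checksum manifest plus a configuration echo from which
every table can be re-derived.

## Known limitations

* The Wald test with trend dispersions has no outlier handling (no
  Cook's-distance analogue) and no empirical-Bayes fold-change shrinkage;
  extreme low-count genes rely on the pseudocount.
* The normal reference at n = 4 is approximate even with trend dispersions;
  calibration was verified at the simulated conditions, not proven.
* The exact Wilcoxon switches to the normal approximation in the presence
  of ties regardless of sample size.
* Over-representation is a plain hypergeometric test on user-supplied sets:
  no term hierarchy, no identifier mapping.
* The one-site IC50 fit assumes independent homoscedastic errors; weighted
  fits are out of scope.
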