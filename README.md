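# ripcouple

Coupled RNA-seq / RIP-seq analysis of RNA-binding-protein target
displacement.

## The problem

RNA-binding proteins (RBPs) such as HuR (ELAVL1) bind AU-rich elements
(AREs) in mRNA 3′-UTRs and stabilize inflammatory transcripts. A
small-molecule RBP inhibitor should *uncouple* a transcript's abundance
from its RBP binding: after stimulation (e.g. LPS in macrophages) induced
transcripts are both upregulated and heavily RBP-bound, and a displacing
drug lowers the binding of a subset of them without abolishing the
transcriptional response. `ripcouple` implements the full desk side of such
a study for computational biologists working from count matrices:

* **Differential expression / binding** — median-of-ratios size factors
  `s_j = median_g K_gj / (∏_j' K_gj')^(1/m)` (rescaled to geometric mean 1),
  a `log2(K/s + 1)` transform, and a per-gene negative-binomial Wald test
  (`Var = μ + αμ²`, method-of-moments dispersion stabilized by a fitted
  mean–dispersion trend `α(μ) = a₀ + a₁/μ`), with Benjamini–Hochberg
  adjustment, PCA and average-linkage/correlation-distance clustering.
* **Coupling analysis** — per-gene contrast scores in transformed space for
  the RNA (input) and RIP (IP) assays; the Pearson *coupling correlation*
  `r = cor(rna_z, rip_z)` over filtered gene sets; the filtering cascade
  `S_stim` (up and RBP-enriched under stimulus), `S_drug` (same under
  stimulus + drug), `S_common`, and the displaced subset `S_displaced`
  (significant IP decrease, drug vs stimulus); Gaussian-KDE difference
  surfaces of the two score scatters on a triangulated grid; hypergeometric
  over-representation against user GMT collections.
* **ARE / 3′-UTR characterization** — overlapping-motif scans for the
  canonical ARE classes (`AUUUA` up to `WWWUAUUUAUWWW`, W = A/U), group
  comparisons of UTR length and ARE count by Wilcoxon rank-sum, and the
  below-average-ARE flag for displaced genes.
* **Bench calculators** — RIP-qPCR fold enrichment `2^−ΔCt`, relative
  expression `2^−ΔΔCt`, one-site IC50 fits
  `y = bottom + (top − bottom)/(1 + x/IC50)` (Hill slope free in the
  four-parameter mode), and Welch's t-test.
* **Synthetic data** — a generator producing paired RNA-seq/RIP-seq/IgG
  count matrices (3 conditions × 4 replicates), 3′-UTR sequences with
  planted AREs, and per-gene ground truth (induction effect β, binding
  effect b with `cor(β, b) = ρ` among responsive∩bound genes, displacement
  flags), so every stage of the pipeline is testable without external data.

## Worked example

```r
library(ripcouple)

exp <- generate_experiment(sim_config(seed = 42))
exp
#> synthetic_experiment: 2000 genes; 36 libraries; 445 responsive, 798 bound,
#> 96 displaced

res <- run_full(run_config(outdir = "demo_run", seed = 42))
res$cascade
#> cascade_result sizes: S_lps=293, S_drug=262, S_common=253, S_displaced=46
#> r over S_lps: 0.795 (n=293)   r over S_drug: 0.593 (n=262)
```

293 genes are both upregulated (log2FC > 1, padj < 0.05) and RBP-enriched
(IP log2FC > 3) under stimulus, and their expression and binding scores are
strongly coupled (r = 0.80). Under stimulus + drug, 262 genes still pass,
253 of them shared, but the coupling drops to r = 0.59: the drug has
displaced transcripts from the protein without silencing them. 46 genes of
`S_common` show a significant IP decrease (drug vs stimulus) — the displaced
core set, written per gene to `demo_run/cascade.tsv` alongside all
differential tables, score tables, the KDE difference surface, ARE
profiles, and a `summary.json` + checksum manifest for provenance.

The bench calculators work standalone:

```r
fold_enrichment(c(21.1, 21.4, 21.2), c(24.3, 24.6, 24.4))
#> $fold_enrichment  9.19   (ΔCt = −3.2, se = 0.79)
```

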