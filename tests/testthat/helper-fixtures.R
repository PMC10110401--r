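# Shared fixture builders (all generated in code; nothing on disk).

toy_sheet <- function(n, condition = "control", assay = "input") {
  data.frame(sample_id = paste0("S", seq_len(n)),
             condition = rep_len(condition, n),
             assay = rep_len(assay, n),
             replicate = ave(seq_len(n), rep_len(condition, n),
                             rep_len(assay, n), FUN = seq_along),
             stringsAsFactors = FALSE)
}

toy_counts <- function(mat, condition = "control", assay = "input") {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  count_matrix(mat, toy_sheet(ncol(mat), condition, assay))
}

# minimal diff_table for cascade tests
toy_diff <- function(genes, lfc, padj) {
  tab <- data.frame(gene = genes, baseMean = 100, log2FoldChange = lfc,
                    lfcSE = 1, stat = lfc, pvalue = padj, padj = padj,
                    dispersion = 0.05, class = NA_character_,
                    stringsAsFactors = FALSE)
  class(tab) <- c("diff_table", "data.frame")
  tab
}

# cache generated experiments across test files (keyed by config)
.exp_cache <- new.env(parent = emptyenv())
cached_experiment <- function(seed = 101, frac_displaced = 0.25, ...) {
  key <- paste(seed, frac_displaced, ..., sep = "_")
  if (is.null(.exp_cache[[key]])) {
    .exp_cache[[key]] <- generate_experiment(
      sim_config(seed = seed, frac_displaced = frac_displaced, ...))
  }
  .exp_cache[[key]]
}

# DE + scores + cascade for one synthetic experiment (the analysis path
# exercised by the coupling recapitulation checks)
run_coupling_analysis <- function(exp) {
  input <- subset_counts(exp$counts, assay = "input")
  ip <- subset_counts(exp$counts, assay = "ip")
  x_rna <- transform_counts(input)
  x_rip <- transform_counts(ip)
  de <- list(
    rna_lps = nb_differential(input, "control", "stimulus"),
    rna_drug = nb_differential(input, "control", "stimulus_drug"),
    rip_lps = nb_differential(ip, "control", "stimulus"),
    rip_drug = nb_differential(ip, "control", "stimulus_drug"),
    rip_drug_vs_lps = nb_differential(ip, "stimulus", "stimulus_drug"))
  pairs_lps <- gene_scores(x_rna, x_rip, c("control", "stimulus"))
  pairs_drug <- gene_scores(x_rna, x_rip, c("control", "stimulus_drug"))
  cascade <- cascade_filter(de$rna_lps, de$rna_drug, de$rip_lps, de$rip_drug,
                            de$rip_drug_vs_lps,
                            pairs_lps = pairs_lps, pairs_drug = pairs_drug)
  list(de = de, pairs_lps = pairs_lps, pairs_drug = pairs_drug,
       cascade = cascade)
}

.an_cache <- new.env(parent = emptyenv())
cached_analysis <- function(seed = 101, frac_displaced = 0.25, ...) {
  key <- paste(seed, frac_displaced, ..., sep = "_")
  if (is.null(.an_cache[[key]])) {
    .an_cache[[key]] <- run_coupling_analysis(
      cached_experiment(seed = seed, frac_displaced = frac_displaced, ...))
  }
  .an_cache[[key]]
}

random_rna <- function(n, alphabet = c("A", "U", "G", "C"),
                       prob = c(0.3, 0.3, 0.2, 0.2)) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}
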