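#' Assemble a full-pipeline run configuration
#'
#' Either simulate the experiment (`simulate = TRUE`, parameters under
#' `sim`) or point the run at existing files (`counts`, `sample_sheet`,
#' and optionally `fasta` and `gmt`).
#'
#' @param outdir Output directory.
#' @param seed Integer seed governing every source of randomness in the run.
#' @param simulate Generate the input data with [generate_experiment()].
#' @param sim List of [sim_config()] overrides (the seed is taken from
#'   `seed`).
#' @param counts,sample_sheet,fasta,gmt Input paths when `simulate = FALSE`
#'   (`fasta`/`gmt` optional).
#' @param rna_lfc,rip_lfc,padj,disp_padj Cascade thresholds (defaults 1, 3,
#'   0.05, 0.05).
#' @param pseudocount,dispersion Passed to [nb_differential()].
#' @param standardize_scores Passed to [gene_scores()].
#' @param grid_n KDE grid nodes per axis for [density_difference()].
#' @param skip_are,skip_ora Skip the ARE/UTR or over-representation stages.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, simulate = TRUE, sim = list(),
                       counts = NULL, sample_sheet = NULL, fasta = NULL,
                       gmt = NULL, rna_lfc = 1, rip_lfc = 3, padj = 0.05,
                       disp_padj = 0.05, pseudocount = 0.5,
                       dispersion = "trend", standardize_scores = FALSE,
                       grid_n = 64, skip_are = FALSE, skip_ora = FALSE) {
  cfg <- as.list(environment())
  if (any(c(rna_lfc, rip_lfc) <= 0) || any(c(padj, disp_padj) <= 0))
    stop("thresholds must be positive")
  if (!simulate) {
    for (f in c("counts", "sample_sheet"))
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]]))
        stop("run_config: ", f, " must exist when simulate = FALSE")
    for (f in c("fasta", "gmt"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        stop("run_config: path does not exist: ", cfg[[f]])
    if (is.null(cfg$fasta) && !skip_are)
      stop("run_config: no FASTA given; the ARE stage needs sequences ",
           "(pass fasta = ... or set skip_are = TRUE)")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "run_config")
}

#' Run the full coupled RNA-seq/RIP-seq analysis
#'
#' Executes (optional) simulation, normalization and transformation per
#' assay, differential testing for the five contrasts, the gene-filtering
#' cascade with coupling correlations and the density-difference surface,
#' ARE/UTR group statistics with the below-average-ARE flag, and (when a
#' gene-set collection is supplied) over-representation of the displaced
#' set. Every intermediate table, a JSON summary and a checksum manifest
#' (with the configuration echo) are written to `config$outdir`; an
#' identical config and seed reproduces identical checksums.
#'
#' A stage failure writes a `FAILED` marker naming the stage and re-raises
#' the error; tables already produced are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summary` (also written as
#'   `summary.json`), `cascade`, `de` (the five `diff_table`s), `manifest`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  stage_name <- "setup"
  on_fail <- function(e) {
    writeLines(c(paste("stage:", stage_name), paste("error:", conditionMessage(e))),
               p("FAILED"))
    stop("pipeline failed at stage '", stage_name, "': ", conditionMessage(e),
         call. = FALSE)
  }
  withCallingHandlers({
    run_full_impl(config, p, function(nm) stage_name <<- nm)
  }, error = on_fail)
}

run_full_impl <- function(config, p, set_stage) {
  set.seed(config$seed)
  set_stage("data")
  if (isTRUE(config$simulate)) {
    sim <- utils::modifyList(config$sim, list(seed = config$seed))
    exp <- generate_experiment(do.call(sim_config, sim))
    counts <- exp$counts
    utrs <- exp$utr_sequences
    write_fixture(exp, p("fixture"))
  } else {
    exp <- NULL
    counts <- read_count_table(config$counts, config$sample_sheet)
    utrs <- if (!is.null(config$fasta)) read_sequences(config$fasta)
  }
  gmt <- if (!is.null(config$gmt)) read_gene_sets(config$gmt)

  set_stage("normalize")
  input <- subset_counts(counts, assay = "input")
  ip <- subset_counts(counts, assay = "ip")
  x_rna <- transform_counts(input)
  x_rip <- transform_counts(ip)

  set_stage("differential")
  de_one <- function(cm, ca, cb) {
    nb_differential(cm, ca, cb, pseudocount = config$pseudocount,
                    dispersion = config$dispersion,
                    lfc_cut = config$rna_lfc, padj_cut = config$padj)
  }
  de <- list(
    rna_lps = de_one(input, "control", "stimulus"),
    rna_drug = de_one(input, "control", "stimulus_drug"),
    rip_lps = de_one(ip, "control", "stimulus"),
    rip_drug = de_one(ip, "control", "stimulus_drug"),
    rip_drug_vs_lps = de_one(ip, "stimulus", "stimulus_drug"))
  for (nm in names(de)) write_diff_table(de[[nm]], p(paste0("de_", nm, ".tsv")))

  set_stage("coupling")
  pairs_lps <- gene_scores(x_rna, x_rip, c("control", "stimulus"),
                           standardize = config$standardize_scores)
  pairs_drug <- gene_scores(x_rna, x_rip, c("control", "stimulus_drug"),
                            standardize = config$standardize_scores)
  for (nm in c("lps", "drug")) {
    utils::write.table(get(paste0("pairs_", nm)), p(paste0("scores_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cascade <- cascade_filter(de$rna_lps, de$rna_drug, de$rip_lps, de$rip_drug,
                            de$rip_drug_vs_lps,
                            thresholds = list(rna_padj = config$padj,
                                              rna_lfc = config$rna_lfc,
                                              rip_padj = config$padj,
                                              rip_lfc = config$rip_lfc,
                                              disp_padj = config$disp_padj),
                            pairs_lps = pairs_lps, pairs_drug = pairs_drug)
  write_cascade(cascade, universe = rownames(counts$counts),
                tsv = p("cascade.tsv"), json = p("cascade_summary.json"))
  surface_note <- NULL
  surface <- tryCatch({
    s <- density_difference(
      pairs_lps[pairs_lps$gene %in% cascade$sets$S_lps, , drop = FALSE],
      pairs_drug[pairs_drug$gene %in% cascade$sets$S_drug, , drop = FALSE],
      grid_n = config$grid_n)
    write_surface(s, p("surface.tsv"), p("surface_triangles.tsv"))
    s
  }, error = function(e) {
    surface_note <<- conditionMessage(e)
    NULL
  })

  are_summary <- NULL
  if (!isTRUE(config$skip_are) && !is.null(utrs)) {
    set_stage("are_utr")
    profiles <- scan_ares(utrs)
    utils::write.table(profiles, p("are_profiles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    labels <- setNames(de$rip_drug_vs_lps$class, de$rip_drug_vs_lps$gene)
    labels <- labels[names(labels) %in% profiles$gene]
    stats_ <- utr_group_stats(profiles, labels)
    utils::write.table(stats_$summary, p("utr_group_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(stats_$tests, p("utr_group_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    disp_in_universe <- intersect(cascade$sets$S_displaced, profiles$gene)
    flag <- if (length(disp_in_universe))
      below_average_flag(disp_in_universe, profiles)
    are_summary <- list(
      n_displaced_profiled = length(disp_in_universe),
      n_below_average = if (is.null(flag)) NA else flag$n_below,
      fraction_below_average = if (is.null(flag)) NA else flag$fraction,
      universe_mean_are = mean(profiles$total))
  }

  ora <- NULL
  if (!isTRUE(config$skip_ora) && !is.null(gmt) &&
      length(cascade$sets$S_displaced)) {
    set_stage("ora")
    ora <- ora_test(cascade$sets$S_displaced, rownames(counts$counts), gmt)
    utils::write.table(ora, p("ora_displaced.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  set_stage("summary")
  summary <- list(
    seed = config$seed,
    n_genes = nrow(counts$counts),
    sizes = as.list(cascade$sizes),
    r_lps = cascade$r_lps$r, r_lps_n = cascade$r_lps$n,
    r_drug = cascade$r_drug$r, r_drug_n = cascade$r_drug$n,
    thresholds = cascade$thresholds,
    score_definition = attr(pairs_lps, "score_definition"),
    transform = x_rna$transform,
    surface = if (is.null(surface)) list(computed = FALSE, note = surface_note)
              else list(computed = TRUE, grid_n = config$grid_n,
                        bandwidth = surface$bandwidth),
    are = are_summary,
    ora_top = if (!is.null(ora) && nrow(ora))
      ora[order(ora$pvalue)[seq_len(min(5, nrow(ora)))],
          c("set", "overlap", "pvalue", "padj")])
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, dataframe = "rows")
  yaml::write_yaml(unclass(config)[setdiff(names(config), "sim")], p("config_echo.yaml"))
  if (length(config$sim)) yaml::write_yaml(config$sim, p("config_sim_echo.yaml"))

  files <- sort(setdiff(list.files(p(), recursive = TRUE), "manifest.tsv"))
  manifest <- data.frame(file = files, md5 = unname(tools::md5sum(p(files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rc_log("run_full: %d outputs in %s", nrow(manifest), p())
  invisible(list(summary = summary, cascade = cascade, de = de,
                 manifest = manifest, outdir = p()))
}
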