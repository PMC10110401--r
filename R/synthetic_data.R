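#' Configuration for the synthetic paired RNA-seq/RIP-seq generator
#'
#' The generator emulates the statistical structure of an RBP-displacement
#' experiment in stimulated macrophages: three conditions (`control`,
#' `stimulus`, `stimulus_drug`) in quadruplicate, a responsive gene subset
#' induced by the stimulus, RBP-binding enrichment in IP libraries that is
#' positively coupled to induction, drug-attenuated binding for a displaced
#' sub-subset, and 3'-UTRs whose length and planted ARE content are higher
#' for bound genes.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_reps Replicates per condition and assay (default 4,
#'   quadruplicate design).
#' @param frac_responsive Fraction of genes induced by the stimulus (0.2).
#' @param effect_scale SD of the log2 induction effects `beta` (1.5).
#' @param induction_mean Mean log2 induction effect of responsive genes (2.5).
#' @param coupling_rho Target correlation between induction and binding
#'   effects among responsive-and-bound genes (0.85).
#' @param frac_bound_responsive,frac_bound_background Probability that a
#'   responsive / non-responsive gene is an RBP target (0.8 / 0.3): stimulus-
#'   induced transcripts are preferentially ARE-containing RBP targets.
#' @param binding_mean,binding_sd Mean and SD of the log2 IP-enrichment
#'   effect of bound genes under stimulation (3.5, 0.8).
#' @param frac_displaced Fraction of bound responsive genes whose IP
#'   enrichment is attenuated under drug (0.25).
#' @param displacement_factor Multiplicative attenuation of the binding
#'   effect under drug for displaced genes, in (0, 1] (0.25).
#' @param drug_effect_sd SD of the extra log2 transcriptional effect of the
#'   drug on responsive genes (0.25); the drug modulates, but does not
#'   abolish, the stimulus response.
#' @param dispersion_shape Lognormal (meanlog, sdlog) for per-gene NB
#'   dispersions, `c(log(0.05), 0.5)`.
#' @param base_mean_params Lognormal (meanlog, sdlog) for per-gene baseline
#'   means, `c(log(100), 1.2)` — the regime of a count matrix already
#'   filtered of near-zero genes.
#' @param lib_size_range Uniform range of per-sample relative depths,
#'   `c(0.7, 1.3)`.
#' @param igg_fraction IgG (mock IP) libraries are a constant,
#'   binding-independent background fraction of the input mean (0.02).
#' @param utr_len_params Lognormal (meanlog, sdlog) of 3'-UTR lengths plus a
#'   positive meanlog shift for bound genes, `c(log(400), 0.6, 0.7)`.
#' @param are_lambda_bound,are_lambda_unbound Poisson means of planted
#'   non-overlapping `AUUUA` pentamers (5 / 1).
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_reps = 4,
                       frac_responsive = 0.2,
                       effect_scale = 1.5,
                       induction_mean = 2.5,
                       coupling_rho = 0.85,
                       frac_bound_responsive = 0.8,
                       frac_bound_background = 0.3,
                       binding_mean = 3.5,
                       binding_sd = 0.8,
                       frac_displaced = 0.25,
                       displacement_factor = 0.25,
                       drug_effect_sd = 0.25,
                       dispersion_shape = c(log(0.05), 0.5),
                       base_mean_params = c(log(100), 1.2),
                       lib_size_range = c(0.7, 1.3),
                       igg_fraction = 0.02,
                       utr_len_params = c(log(400), 0.6, 0.7),
                       are_lambda_bound = 5,
                       are_lambda_unbound = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  stop_if <- function(bad, msg) if (bad) stop("sim_config: ", msg, call. = FALSE)
  stop_if(n_genes < 1 || n_genes != round(n_genes), "n_genes must be a positive integer")
  stop_if(n_reps < 2 || n_reps != round(n_reps), "n_reps must be an integer >= 2")
  for (f in c("frac_responsive", "frac_bound_responsive", "frac_bound_background",
              "frac_displaced")) {
    v <- cfg[[f]]
    stop_if(!is.finite(v) || v < 0 || v > 1, paste(f, "must be in [0, 1]"))
  }
  stop_if(abs(coupling_rho) > 1, "coupling_rho must be in [-1, 1]")
  stop_if(displacement_factor <= 0 || displacement_factor > 1,
          "displacement_factor must be in (0, 1]")
  stop_if(effect_scale < 0 || binding_sd < 0 || drug_effect_sd < 0,
          "scale parameters must be non-negative")
  stop_if(length(dispersion_shape) != 2 || dispersion_shape[2] < 0,
          "dispersion_shape must be c(meanlog, sdlog)")
  stop_if(length(base_mean_params) != 2, "base_mean_params must be c(meanlog, sdlog)")
  stop_if(length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
            diff(lib_size_range) < 0, "lib_size_range must be a positive range")
  stop_if(igg_fraction <= 0 || igg_fraction > 1, "igg_fraction must be in (0, 1]")
  stop_if(length(utr_len_params) != 3 || utr_len_params[2] < 0,
          "utr_len_params must be c(meanlog, sdlog, bound_shift)")
  stop_if(are_lambda_bound < 0 || are_lambda_unbound < 0, "ARE lambdas must be >= 0")
  stop_if(!is.finite(seed) || seed != round(seed), "seed must be an integer")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Generate a paired RNA-seq/RIP-seq experiment with ground truth
#'
#' Draws per-gene truth parameters, then integer counts for every
#' (condition x assay) cell, plus 3'-UTR sequences with planted `AUUUA`
#' pentamers in a GC-weighted (AU-poor) background.
#'
#' The mean model, per gene g and condition c with relative depth `d_j`:
#' input `mu_gc = base_g * 2^(beta_g [c != control] + delta_g [c = drug])`;
#' IP `mu_gc * 2^(b_gc)` with
#' `b_gc = binding_g * [c != control] * a_gc`, where `a_gc =
#' displacement_factor` iff the gene is displaced and `c = stimulus_drug`,
#' else 1 (binding enrichment accompanies stimulation, and the drug
#' attenuates it for displaced genes); IgG `igg_fraction * mu_gc`.
#' Counts are `NB(mean = mu * d_j, Var = mu + alpha_g mu^2)`.
#'
#' `(beta, binding)` are drawn jointly (bivariate normal) so their
#' correlation among responsive-and-bound genes equals `coupling_rho` in
#' expectation. Draws are ordered truth, input counts (control, stimulus,
#' drug), IP counts (control, stimulus, drug), IgG counts, so experiments
#' differing only in `frac_displaced` share identical control/stimulus
#' counts at the same seed (common random numbers).
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_experiment`: list with `counts`
#'   (a [count_matrix()] over all 3 conditions x 3 assays x `n_reps`),
#'   `utr_sequences` (named character), `annotation` (gene, utr_length,
#'   planted and scanned ARE counts), `truth` (per-gene parameters) and
#'   `config`.
#' @export
generate_experiment <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  nr <- config$n_reps
  genes <- sprintf("gene%05d", seq_len(ng))

  # --- truth -----------------------------------------------------------
  responsive <- stats::runif(ng) < config$frac_responsive
  p_bound <- ifelse(responsive, config$frac_bound_responsive,
                    config$frac_bound_background)
  bound <- stats::runif(ng) < p_bound
  beta <- numeric(ng)
  binding <- numeric(ng)
  rb <- responsive & bound
  z1 <- stats::rnorm(sum(rb))
  z2 <- config$coupling_rho * z1 +
    sqrt(1 - config$coupling_rho^2) * stats::rnorm(sum(rb))
  beta[rb] <- config$induction_mean + config$effect_scale * z1
  binding[rb] <- config$binding_mean + config$binding_sd * z2
  ro <- responsive & !bound
  beta[ro] <- stats::rnorm(sum(ro), config$induction_mean, config$effect_scale)
  bo <- !responsive & bound
  binding[bo] <- stats::rnorm(sum(bo), config$binding_mean, config$binding_sd)
  displaced <- rb & (stats::runif(ng) < config$frac_displaced)
  delta <- stats::rnorm(ng, 0, config$drug_effect_sd) * responsive
  base <- stats::rlnorm(ng, config$base_mean_params[1], config$base_mean_params[2])
  dispersion <- stats::rlnorm(ng, config$dispersion_shape[1], config$dispersion_shape[2])
  utr_len <- round(stats::rlnorm(ng, config$utr_len_params[1] +
                                   config$utr_len_params[3] * bound,
                                 config$utr_len_params[2]))
  are_lambda <- ifelse(bound, config$are_lambda_bound, config$are_lambda_unbound)
  planted <- stats::rpois(ng, are_lambda)
  utr_len <- pmax(utr_len, 5L * planted + 10L)
  utr <- vapply(seq_len(ng), function(i) plant_ares(utr_len[i], planted[i]),
                character(1))
  names(utr) <- genes

  # --- counts ----------------------------------------------------------
  conds <- rc_conditions
  sheet <- expand.grid(replicate = seq_len(nr), condition = conds,
                       assay = rc_assays, stringsAsFactors = FALSE)
  sheet$sample_id <- paste(sheet$assay, sheet$condition, sheet$replicate, sep = "_")
  sheet <- sheet[, c("sample_id", "condition", "assay", "replicate")]
  depth <- stats::runif(nrow(sheet), config$lib_size_range[1], config$lib_size_range[2])

  input_mu <- function(cc)
    base * 2^(beta * (cc != "control") + delta * (cc == "stimulus_drug"))
  ip_mu <- function(cc) {
    atten <- ifelse(displaced & cc == "stimulus_drug", config$displacement_factor, 1)
    input_mu(cc) * 2^(binding * (cc != "control") * atten)
  }
  igg_mu <- function(cc) config$igg_fraction * input_mu(cc)

  counts <- matrix(0L, ng, nrow(sheet), dimnames = list(genes, sheet$sample_id))
  for (asy in rc_assays) {           # draw order fixed: input, ip, igg
    muf <- switch(asy, input = input_mu, ip = ip_mu, igg = igg_mu)
    for (cc in conds) {              # and control, stimulus, stimulus_drug
      j <- which(sheet$assay == asy & sheet$condition == cc)
      mu <- outer(muf(cc), depth[j])
      counts[, j] <- matrix(stats::rnbinom(ng * length(j), mu = mu,
                                           size = 1 / dispersion), ng)
    }
  }

  truth <- data.frame(
    gene = genes, responsive = responsive, beta = beta, bound = bound,
    binding_effect = binding, displaced = displaced, delta = delta,
    planted_are_count = planted, utr_length = nchar(utr),
    dispersion = dispersion, base_mean = base, stringsAsFactors = FALSE)

  profile <- scan_ares(utr)
  annotation <- data.frame(gene = genes, utr_length = nchar(utr),
                           planted_are_count = planted,
                           are_total = profile$total, stringsAsFactors = FALSE)

  rc_log("generate_experiment: %d genes, %d samples, seed %d",
         ng, nrow(sheet), config$seed)
  structure(list(counts = count_matrix(counts, sheet),
                 utr_sequences = utr, annotation = annotation,
                 truth = truth, config = config),
            class = "synthetic_experiment")
}

# one UTR: AU-poor (GC-weighted) background with n_sites non-overlapping
# AUUUA pentamers planted at random positions
plant_ares <- function(len, n_sites) {
  stopifnot(len >= 5 * n_sites)
  bg <- sample(c("A", "U", "G", "C"), len, replace = TRUE,
               prob = c(0.12, 0.12, 0.38, 0.38))
  if (n_sites > 0) {
    u <- sort(sample.int(len - 4L * n_sites, n_sites))
    starts <- u + 4L * (seq_len(n_sites) - 1L)
    for (s in starts) bg[s:(s + 4L)] <- c("A", "U", "U", "U", "A")
  }
  paste(bg, collapse = "")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("synthetic_experiment:", x$config$n_genes, "genes;",
      ncol(x$counts$counts), "libraries;",
      sum(x$truth$responsive), "responsive,", sum(x$truth$bound), "bound,",
      sum(x$truth$displaced), "displaced\n")
  invisible(x)
}

#' Write a synthetic experiment to a fixture directory
#'
#' Emits the counts (TSV and MatrixMarket dialects), sample sheet, 3'-UTR
#' FASTA, annotation and truth tables, and a YAML echo of the configuration,
#' plus a manifest of paths and MD5 checksums.
#'
#' @param exp A `synthetic_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a data frame manifest (`file`, `md5`); also written to
#'   `manifest.tsv` in `dir`.
#' @export
write_fixture <- function(exp, dir) {
  stopifnot(inherits(exp, "synthetic_experiment"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create fixture directory: ", dir)
  }
  p <- function(...) file.path(dir, ...)
  write_count_table(exp$counts, p("counts.tsv"), sample_sheet = p("samples.tsv"))
  write_count_table(exp$counts, p("counts.mtx"))
  write_sequences(exp$utr_sequences, p("utrs.fasta"))
  utils::write.table(exp$annotation, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(exp$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(exp$config), p("config.yaml"))
  files <- c("counts.tsv", "counts.mtx", "counts.mtx.rownames",
             "counts.mtx.colnames", "samples.tsv", "utrs.fasta",
             "annotation.tsv", "truth.tsv", "config.yaml")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(p(files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
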