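#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making libraries comparable: for each sample
#' j, `s_j` is the median over qualifying genes (rows with all-positive
#' counts) of `K_gj / geomean_g`, where `geomean_g` is the geometric mean of
#' row g; the vector is then rescaled to geometric mean 1.
#'
#' @param counts A [count_matrix()] or plain integer matrix.
#' @return Named numeric vector of positive size factors whose geometric
#'   mean is 1.
#' @export
estimate_size_factors <- function(counts) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(k) < 1) stop("no samples")
  log_geo <- rowMeans(log(k))
  ok <- is.finite(log_geo)
  if (!any(ok))
    stop("no gene has all-positive counts; filter the matrix to expressed ",
         "genes before normalization")
  s <- apply(k[ok, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo[ok]))
  })
  s <- s / exp(mean(log(s)))
  setNames(s, colnames(k))
}

#' Log-scale transform of normalized counts
#'
#' A monotone variance-flattening transform of the normalized counts:
#' `log2(K_gj / s_j + 1)`. The transform tag travels with the result so
#' downstream outputs can declare it.
#'
#' @param counts A [count_matrix()] (or matrix).
#' @param size_factors Positive per-sample factors; estimated with
#'   [estimate_size_factors()] when missing.
#' @return Object of class `transformed_matrix`: list with `x` (genes x
#'   samples real matrix), `samples` (metadata if available) and
#'   `transform` tag.
#' @export
transform_counts <- function(counts, size_factors = NULL) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  samples <- if (inherits(counts, "count_matrix")) counts$samples else NULL
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (length(size_factors) != ncol(k))
    stop("size_factors length ", length(size_factors),
         " does not match ", ncol(k), " samples")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  x <- log2(sweep(k, 2, size_factors, "/") + 1)
  structure(list(x = x, samples = samples, transform = "log2(normalized + 1)"),
            class = "transformed_matrix")
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat("transformed_matrix [", x$transform, "]: ", nrow(x$x), " genes x ",
      ncol(x$x), " samples\n", sep = "")
  invisible(x)
}

resolve_selector <- function(sel, counts) {
  samples <- if (inherits(counts, "count_matrix")) counts$samples else NULL
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (is.character(sel)) {
    if (!is.null(samples) && all(sel %in% samples$condition))
      return(which(samples$condition %in% sel))
    idx <- match(sel, colnames(k))
    if (anyNA(idx)) stop("unknown sample(s): ", paste(sel[is.na(idx)], collapse = ", "))
    return(idx)
  }
  if (is.logical(sel)) return(which(sel))
  as.integer(sel)
}

#' Negative-binomial Wald test for one contrast
#'
#' Per gene: normalized group means, `log2fc = log2((m_B + c)/(m_A + c))`
#' with pseudocount `c`; NB dispersion (`Var = mu + alpha mu^2`) estimated by
#' method of moments pooled across the two groups and, by default, replaced
#' by the fitted mean-dispersion trend `alpha(mu) = a0 + a1/mu` (the
#' per-gene moment estimate at n = 4 vs 4 has so few degrees of freedom that
#' a Wald test against the normal reference is badly anticonservative);
#' delta-method standard error; two-sided normal p; BH-adjusted p.
#'
#' A gene with zero counts in every sample of both groups is reported as
#' `log2fc = 0`, `p = 1` by convention.
#'
#' @param counts A [count_matrix()] or integer matrix.
#' @param group_a,group_b Disjoint sample selectors (condition name(s),
#'   sample ids, logical mask or indices), each with >= 2 samples. `group_a`
#'   is the reference: positive `log2fc` means higher in `group_b`.
#' @param size_factors Optional; estimated from the selected samples when
#'   missing.
#' @param pseudocount Pseudocount `c` in the fold change (default 0.5).
#' @param dispersion One of `"trend"` (default) or `"genewise"`.
#' @param alpha_min Dispersion floor (default 1e-8).
#' @param lfc_cut,padj_cut Thresholds handed to [classify_degs()].
#' @return A `diff_table` data frame: `gene`, `baseMean`, `log2FoldChange`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`, `dispersion`, `class`.
#' @export
nb_differential <- function(counts, group_a, group_b, size_factors = NULL,
                            pseudocount = 0.5,
                            dispersion = c("trend", "genewise"),
                            alpha_min = 1e-8, lfc_cut = 1, padj_cut = 0.05) {
  dispersion <- match.arg(dispersion)
  k_all <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  ia <- resolve_selector(group_a, counts)
  ib <- resolve_selector(group_b, counts)
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs >= 2 samples (singleton groups are not testable)")
  if (inherits(counts, "count_matrix")) {
    asy <- unique(counts$samples$assay[c(ia, ib)])
    if (length(asy) > 1)
      stop("groups mix assays (", paste(asy, collapse = ", "),
           "); contrast within one assay")
  }
  sel <- c(ia, ib)
  k <- k_all[, sel, drop = FALSE]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(k)
  if (length(size_factors) != length(sel))
    stop("size_factors must cover the selected samples")
  kn <- sweep(k, 2, size_factors, "/")
  a_idx <- seq_along(ia)
  b_idx <- length(ia) + seq_along(ib)
  na <- length(ia); nb <- length(ib)
  m_a <- rowMeans(kn[, a_idx, drop = FALSE])
  m_b <- rowMeans(kn[, b_idx, drop = FALSE])
  base_mean <- rowMeans(kn)

  # method-of-moments dispersion pooled across the two groups
  ss <- rowSums((kn[, a_idx, drop = FALSE] - m_a)^2) +
    rowSums((kn[, b_idx, drop = FALSE] - m_b)^2)
  s2 <- ss / (na + nb - 2)
  alpha_mom <- (s2 - base_mean) / base_mean^2
  alpha_mom[!is.finite(alpha_mom)] <- NA_real_

  alpha <- switch(dispersion,
    genewise = pmax(alpha_mom, alpha_min),
    trend = {
      use <- is.finite(alpha_mom) & base_mean > 0
      if (sum(use) >= 10 && stats::var(1 / base_mean[use]) > 0) {
        fit <- stats::lm(alpha_mom[use] ~ I(1 / base_mean[use]))
        a0 <- unname(stats::coef(fit)[1]); a1 <- unname(stats::coef(fit)[2])
        pmax(a0 + a1 / base_mean, alpha_min)
      } else {
        # too few genes for a trend: fall back to one pooled value
        pooled <- mean(alpha_mom[is.finite(alpha_mom)])
        rep(pmax(if (is.finite(pooled)) pooled else alpha_min, alpha_min), nrow(k))
      }
    })
  alpha[is.na(alpha)] <- alpha_min

  c0 <- pseudocount
  lfc <- log2((m_b + c0) / (m_a + c0))
  v_a <- (m_a + alpha * m_a^2) / na
  v_b <- (m_b + alpha * m_b^2) / nb
  se <- sqrt(v_a / (m_a + c0)^2 + v_b / (m_b + c0)^2) / log(2)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  allzero <- m_a == 0 & m_b == 0
  lfc[allzero] <- 0
  stat[allzero] <- 0
  p[allzero] <- 1
  se[allzero] <- NA_real_
  tab <- data.frame(gene = rownames(k), baseMean = base_mean,
                    log2FoldChange = lfc, lfcSE = se, stat = stat,
                    pvalue = p, padj = adjust_bh(p), dispersion = alpha,
                    class = NA_character_, stringsAsFactors = FALSE,
                    row.names = NULL)
  tab <- classify_degs(tab, lfc_cut = lfc_cut, padj_cut = padj_cut)
  class(tab) <- c("diff_table", "data.frame")
  attr(tab, "contrast") <- list(reference = ia, treatment = ib,
                                dispersion = dispersion, pseudocount = c0)
  tab
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m / j) p_(j)`, capped at 1, returned in input
#' order; computed via [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (finite).
#' @return Adjusted values in `[0, 1]`, same order as input.
#' @export
adjust_bh <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify differential genes
#'
#' `up` iff `padj < padj_cut` and `log2fc > lfc_cut`; `down` iff
#' `padj < padj_cut` and `log2fc < -lfc_cut`; otherwise `nd`. Inequalities
#' are strict, so boundary values are `nd`.
#'
#' @param table A `diff_table` with `padj` populated.
#' @param lfc_cut Positive log2 fold-change cutoff (default 1).
#' @param padj_cut Adjusted-p cutoff (default 0.05).
#' @return The table with `class` filled.
#' @export
classify_degs <- function(table, lfc_cut = 1, padj_cut = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("log2FoldChange", "padj") %in% names(table)))
  if (lfc_cut <= 0) stop("lfc_cut must be positive")
  cls <- rep("nd", nrow(table))
  sig <- !is.na(table$padj) & table$padj < padj_cut
  cls[sig & table$log2FoldChange > lfc_cut] <- "up"
  cls[sig & table$log2FoldChange < -lfc_cut] <- "down"
  table$class <- cls
  attr(table, "thresholds") <- c(lfc_cut = lfc_cut, padj_cut = padj_cut)
  table
}

#' Write a differential table as TSV
#'
#' Fixed column order (`gene`, `baseMean`, `log2FoldChange`, `lfcSE`,
#' `stat`, `pvalue`, `padj`, `class`) for interoperability.
#'
#' @param table A `diff_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diff_table <- function(table, path) {
  cols <- c("gene", "baseMean", "log2FoldChange", "lfcSE", "stat",
            "pvalue", "padj", "class")
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' PCA summary of a transformed matrix
#'
#' Principal components of the sample-by-gene matrix after gene-wise
#' centering. Variance fractions sum to 1 over all components.
#'
#' @param x A `transformed_matrix` (or genes x samples matrix).
#' @param n_components How many sample scores to return (default all).
#' @return List with `variance_fraction` (all components) and `scores`
#'   (samples x `n_components`).
#' @export
pca_summary <- function(x, n_components = NULL) {
  m <- if (inherits(x, "transformed_matrix")) x$x else as.matrix(x)
  if (ncol(m) < 2) stop("need >= 2 samples")
  if (all(apply(m, 1, stats::var) == 0))
    stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_components)) length(vf) else min(n_components, ncol(pc$x))
  list(variance_fraction = vf, scores = pc$x[, seq_len(k), drop = FALSE])
}

#' Average-linkage (UPGMA) clustering with correlation distance
#'
#' Agglomerates genes or samples with distance `d = 1 - Pearson r` and
#' average linkage, the combination used for expression heatmaps.
#'
#' @param x A `transformed_matrix` (or matrix).
#' @param axis `"genes"` (rows) or `"samples"` (columns).
#' @return An [stats::hclust] tree (merge order, heights, leaf order).
#' @export
hierarchical_cluster <- function(x, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- if (inherits(x, "transformed_matrix")) x$x else as.matrix(x)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2) stop("need >= 2 items to cluster")
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    nm <- rownames(m)[v == 0]
    if (is.null(nm)) nm <- which(v == 0)
    stop("zero-variance item(s), correlation distance undefined: ",
         paste(utils::head(nm, 5), collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  stats::hclust(d, method = "average")
}
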