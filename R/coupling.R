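#' Per-gene expression and binding contrast scores
#'
#' For each assay, the per-gene score is the difference of condition means
#' of the transformed matrix (treated minus control) — one value per gene
#' per comparison. With `standardize = TRUE` the scores are additionally
#' z-scored across genes within each assay; Pearson correlations between the
#' two coordinates are invariant to this choice. A gene whose row is
#' constant in an assay is flagged and scored 0 in that assay.
#'
#' @param x_rna,x_rip `transformed_matrix` objects sharing gene ids, with
#'   sample metadata carrying `condition`.
#' @param contrast Length-2 character: `c(control_condition,
#'   treated_condition)`.
#' @param standardize Standardize scores across genes (default `FALSE`).
#' @return A `gene_score_pairs` data frame: `gene`, `rna_z`, `rip_z`,
#'   `rna_flat`, `rip_flat`, with a `score_definition` attribute.
#' @export
gene_scores <- function(x_rna, x_rip, contrast, standardize = FALSE) {
  stopifnot(inherits(x_rna, "transformed_matrix"),
            inherits(x_rip, "transformed_matrix"),
            length(contrast) == 2)
  if (!identical(rownames(x_rna$x), rownames(x_rip$x)))
    stop("the two matrices must share the same gene ids in the same order")
  one <- function(tm) {
    if (is.null(tm$samples)) stop("transformed matrix lacks sample metadata")
    ctrl <- tm$samples$condition == contrast[1]
    trt <- tm$samples$condition == contrast[2]
    if (!any(ctrl) || !any(trt))
      stop("contrast condition(s) absent: ",
           paste(contrast[!c(any(ctrl), any(trt))], collapse = ", "))
    d <- rowMeans(tm$x[, trt, drop = FALSE]) -
      rowMeans(tm$x[, ctrl, drop = FALSE])
    flat <- apply(tm$x[, ctrl | trt, drop = FALSE], 1, stats::var) == 0
    d[flat] <- 0
    if (standardize && stats::sd(d[!flat]) > 0) {
      d[!flat] <- (d[!flat] - mean(d[!flat])) / stats::sd(d[!flat])
      d[flat] <- 0
    }
    list(d = d, flat = flat)
  }
  rna <- one(x_rna)
  rip <- one(x_rip)
  out <- data.frame(gene = rownames(x_rna$x), rna_z = rna$d, rip_z = rip$d,
                    rna_flat = rna$flat, rip_flat = rip$flat,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gene_score_pairs", "data.frame")
  attr(out, "score_definition") <-
    paste0("difference of condition means (", contrast[2], " - ", contrast[1],
           ") of ", x_rna$transform,
           if (standardize) ", z-scored across genes" else "")
  attr(out, "contrast") <- contrast
  out
}

#' Expression-binding coupling correlation
#'
#' Pearson correlation between the RNA-seq and RIP-seq scores of a gene
#' subset, with the two-sided p-value from the t reference with n - 2
#' degrees of freedom (via [stats::cor.test()]). Its decrease under drug
#' treatment quantifies displacement of transcripts from the RBP.
#'
#' @param pairs A `gene_score_pairs` data frame.
#' @param subset Optional character vector of gene ids (default: all pairs).
#' @return List with `r`, `p`, `n`.
#' @export
coupling_correlation <- function(pairs, subset = NULL) {
  stopifnot(is.data.frame(pairs))
  d <- if (is.null(subset)) pairs else pairs[pairs$gene %in% subset, , drop = FALSE]
  if (nrow(d) < 3)
    stop("need >= 3 genes for a correlation (got ", nrow(d), ")")
  if (stats::sd(d$rna_z) == 0 || stats::sd(d$rip_z) == 0)
    stop("zero variance in one of the score coordinates")
  ct <- stats::cor.test(d$rna_z, d$rip_z, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}

select_genes <- function(table, padj_cut, lfc_cut, direction) {
  sig <- !is.na(table$padj) & table$padj < padj_cut
  hit <- switch(direction,
                up = sig & table$log2FoldChange > lfc_cut,
                down = sig & table$log2FoldChange < lfc_cut)
  sort(table$gene[hit])
}

#' The gene-filtering cascade
#'
#' Reproduces the integrative filtering workflow: genes upregulated at the
#' transcriptome level and enriched in the RBP IP under stimulus
#' (`S_lps`), the analogous set under stimulus + drug (`S_drug`), their
#' intersection (`S_common`), and the displaced subset of `S_common` whose
#' IP enrichment significantly decreases under drug relative to stimulus
#' (`S_displaced`). Coupling correlations over `S_lps` and `S_drug` are
#' attached when score pairs are supplied.
#'
#' @param rna_lps,rna_drug RNA-seq `diff_table`s (stimulus vs control,
#'   stimulus+drug vs control).
#' @param rip_lps,rip_drug RIP-seq (IP-library) `diff_table`s for the same
#'   contrasts.
#' @param rip_drug_vs_lps RIP-seq `diff_table` for stimulus+drug vs stimulus.
#' @param thresholds List with `rna_padj` (0.05), `rna_lfc` (1), `rip_padj`
#'   (0.05), `rip_lfc` (3), `disp_padj` (0.05); displacement additionally
#'   requires `log2FoldChange < 0` in `rip_drug_vs_lps`. Inequalities strict.
#' @param pairs_lps,pairs_drug Optional `gene_score_pairs` for the two
#'   contrasts; when given, correlations are computed with
#'   [coupling_correlation()] on sets with >= 3 genes (reported with
#'   `r = NA, n` otherwise).
#' @return Object of class `cascade_result`: list with `sets` (sorted gene
#'   id vectors `S_lps`, `S_drug`, `S_common`, `S_displaced`), `sizes`,
#'   `r_lps`, `r_drug`, `thresholds`.
#' @export
cascade_filter <- function(rna_lps, rna_drug, rip_lps, rip_drug,
                           rip_drug_vs_lps,
                           thresholds = list(rna_padj = 0.05, rna_lfc = 1,
                                             rip_padj = 0.05, rip_lfc = 3,
                                             disp_padj = 0.05),
                           pairs_lps = NULL, pairs_drug = NULL) {
  tabs <- list(rna_lps = rna_lps, rna_drug = rna_drug, rip_lps = rip_lps,
               rip_drug = rip_drug, rip_drug_vs_lps = rip_drug_vs_lps)
  uni <- sort(tabs[[1]]$gene)
  for (nm in names(tabs)[-1]) {
    g <- sort(tabs[[nm]]$gene)
    if (!identical(uni, g)) {
      d <- c(setdiff(uni, g), setdiff(g, uni))
      stop("tables do not share one gene universe; symmetric difference ",
           "of rna_lps and ", nm, ": ",
           paste(utils::head(d, 10), collapse = ", "),
           if (length(d) > 10) sprintf(" (and %d more)", length(d) - 10) else "")
    }
  }
  th <- utils::modifyList(list(rna_padj = 0.05, rna_lfc = 1, rip_padj = 0.05,
                               rip_lfc = 3, disp_padj = 0.05), thresholds)
  s_lps <- intersect(
    select_genes(rna_lps, th$rna_padj, th$rna_lfc, "up"),
    select_genes(rip_lps, th$rip_padj, th$rip_lfc, "up"))
  s_drug <- intersect(
    select_genes(rna_drug, th$rna_padj, th$rna_lfc, "up"),
    select_genes(rip_drug, th$rip_padj, th$rip_lfc, "up"))
  s_common <- intersect(s_lps, s_drug)
  s_disp <- intersect(s_common,
                      select_genes(rip_drug_vs_lps, th$disp_padj, 0, "down"))
  sets <- lapply(list(S_lps = s_lps, S_drug = s_drug, S_common = s_common,
                      S_displaced = s_disp), sort)
  cor_or_na <- function(pairs, set) {
    if (is.null(pairs)) return(NULL)
    if (length(set) < 3) return(list(r = NA_real_, p = NA_real_, n = length(set)))
    coupling_correlation(pairs, set)
  }
  structure(list(sets = sets,
                 sizes = vapply(sets, length, integer(1)),
                 r_lps = cor_or_na(pairs_lps, sets$S_lps),
                 r_drug = cor_or_na(pairs_drug, sets$S_drug),
                 thresholds = th),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("cascade_result sizes:",
      paste(names(x$sizes), x$sizes, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$r_lps))
    cat(sprintf("r over S_lps: %.3f (n=%d)   r over S_drug: %.3f (n=%d)\n",
                x$r_lps$r, x$r_lps$n, x$r_drug$r, x$r_drug$n))
  invisible(x)
}

#' Write a cascade result (per-gene membership TSV + JSON summary)
#'
#' @param x A `cascade_result`.
#' @param universe Character vector of all gene ids (one row each).
#' @param tsv,json Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_cascade <- function(x, universe, tsv = NULL, json = NULL) {
  out <- character()
  if (!is.null(tsv)) {
    tab <- data.frame(gene = sort(universe), stringsAsFactors = FALSE)
    for (nm in names(x$sets)) tab[[nm]] <- tab$gene %in% x$sets[[nm]]
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, tsv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(sizes = as.list(x$sizes),
                              r_lps = x$r_lps, r_drug = x$r_drug,
                              thresholds = x$thresholds),
                         json, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    out <- c(out, json)
  }
  invisible(out)
}

#' Overlap region counts of two or three gene sets
#'
#' Counts for every inclusion-exclusion region of a Venn diagram; region
#' counts sum to the size of the union.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector, one entry per region; exclusive regions are
#'   named `"<set>"`, joint ones `"<set1>&<set2>"` etc.
#' @export
set_overlaps <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3)
    stop("set_overlaps supports 2 or 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, function(row) paste(names(sets)[row], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&", simplify = TRUE)
  }))
  counts <- setNames(integer(length(combos)), combos)
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Difference between two score-scatter densities
#'
#' Gaussian-kernel 2D densities of two `gene_score_pairs` scatters,
#' evaluated on a shared regular grid, each normalized to integrate to 1
#' (trapezoid rule); the nodewise difference `A - B` is the quantity
#' rendered as a 3D surface. Bandwidths are Silverman's rule per axis on the
#' pooled points; the grid spans the pooled 1%-99% quantile window padded by
#' 3 bandwidths. A triangulation of the regular grid (two triangles per
#' cell, node indices row-major) is returned for surface rendering; it is a
#' representation device only — integration uses the trapezoid rule.
#'
#' @param pairs_a,pairs_b `gene_score_pairs` (>= 10 rows each, not
#'   collinear).
#' @param grid_n Nodes per axis (default 64).
#' @param bandwidth Optional length-2 override of the per-axis bandwidths.
#' @param pad_bandwidths Window padding in bandwidth units (default 3).
#' @param window_quantiles Pooled quantile window (default `c(0.01, 0.99)`).
#' @return Object of class `difference_surface`: list with `grid` (node
#'   data frame `x`, `y`), `density_a`, `density_b`, `difference` (per
#'   node), `triangles` (integer matrix, 3 columns), `bandwidth`.
#' @export
density_difference <- function(pairs_a, pairs_b, grid_n = 64,
                               bandwidth = NULL, pad_bandwidths = 3,
                               window_quantiles = c(0.01, 0.99)) {
  pts <- function(p) cbind(p$rna_z, p$rip_z)
  a <- pts(pairs_a); b <- pts(pairs_b)
  for (nm in list(list(a, "pairs_a"), list(b, "pairs_b"))) {
    m <- nm[[1]]
    if (nrow(m) < 10) stop(nm[[2]], ": need >= 10 points")
    if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0 ||
        abs(stats::cor(m[, 1], m[, 2])) > 1 - 1e-12)
      stop(nm[[2]], ": degenerate (collinear) scatter")
  }
  pooled <- rbind(a, b)
  silverman <- function(v) {
    n <- length(v)
    0.9 * min(stats::sd(v), stats::IQR(v) / 1.34) * n^(-1 / 5)
  }
  h <- if (is.null(bandwidth)) apply(pooled, 2, silverman) else rep(bandwidth, length.out = 2)
  if (any(h <= 0)) stop("bandwidths must be positive")
  lo <- apply(pooled, 2, stats::quantile, window_quantiles[1]) - pad_bandwidths * h
  hi <- apply(pooled, 2, stats::quantile, window_quantiles[2]) + pad_bandwidths * h
  gx <- seq(lo[1], hi[1], length.out = grid_n)
  gy <- seq(lo[2], hi[2], length.out = grid_n)

  kde <- function(m) {
    # product Gaussian kernel, evaluated as outer products per axis
    kx <- outer(gx, m[, 1], function(g, x) stats::dnorm((g - x) / h[1]) / h[1])
    ky <- outer(gy, m[, 2], function(g, y) stats::dnorm((g - y) / h[2]) / h[2])
    dens <- kx %*% t(ky) / nrow(m)        # grid_n x grid_n, [ix, iy]
    wx <- trapezoid_weights(gx); wy <- trapezoid_weights(gy)
    dens / as.numeric(wx %*% dens %*% wy) # renormalize to integral 1
  }
  da <- kde(a)
  db <- kde(b)
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)  # x fastest
  structure(list(grid = grid,
                 density_a = as.vector(da), density_b = as.vector(db),
                 difference = as.vector(da) - as.vector(db),
                 triangles = grid_triangles(grid_n, grid_n),
                 bandwidth = h,
                 window = cbind(lo = lo, hi = hi)),
            class = "difference_surface")
}

trapezoid_weights <- function(g) {
  n <- length(g)
  w <- c(diff(g), 0) / 2 + c(0, diff(g)) / 2
  matrix(w, nrow = 1)[1, ]
}

# two triangles per grid cell; node index = ix + (iy - 1) * nx (x fastest)
grid_triangles <- function(nx, ny) {
  ix <- rep(seq_len(nx - 1), ny - 1)
  iy <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- ix + (iy - 1) * nx
  v10 <- v00 + 1
  v01 <- v00 + nx
  v11 <- v01 + 1
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' Write a difference surface (node TSV + triangle list)
#'
#' @param surface A `difference_surface`.
#' @param tsv Path for the node table `(x, y, density_a, density_b,
#'   difference)`.
#' @param triangles Optional path for the triangle index list.
#' @return Invisibly, the paths written.
#' @export
write_surface <- function(surface, tsv, triangles = NULL) {
  tab <- data.frame(surface$grid, density_a = surface$density_a,
                    density_b = surface$density_b,
                    difference = surface$difference)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- tsv
  if (!is.null(triangles)) {
    utils::write.table(as.data.frame(surface$triangles), triangles,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- c(out, triangles)
  }
  invisible(out)
}

#' Gene-set over-representation (hypergeometric) test
#'
#' For each set in the collection, the upper-tail hypergeometric probability
#' of observing at least the overlap between `hits` and the set within
#' `universe`, BH-adjusted across the collection.
#'
#' @param hits Character vector of hit genes (must lie in `universe`).
#' @param universe Character vector of all testable genes.
#' @param collection A `gene_set_collection` (members are intersected with
#'   the universe).
#' @return Data frame: `set`, `description`, `set_size`, `overlap`,
#'   `expected`, `pvalue`, `padj`.
#' @export
ora_test <- function(hits, universe, collection) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hits <- unique(hits)
  out_of <- setdiff(hits, universe)
  if (length(out_of))
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(out_of, 5), collapse = ", "))
  n_u <- length(universe)
  n_h <- length(hits)
  desc <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    k <- length(intersect(hits, members))
    m <- length(members)
    p <- if (k == 0) 1 else stats::phyper(k - 1, m, n_u - m, n_h, lower.tail = FALSE)
    data.frame(set = nm,
               description = if (!is.null(desc)) desc[[nm]] else "",
               set_size = m, overlap = k, expected = n_h * m / n_u,
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(), description = character(),
                      set_size = integer(), overlap = integer(),
                      expected = numeric(), pvalue = numeric(),
                      padj = numeric(), stringsAsFactors = FALSE)
  } else {
    out$padj <- adjust_bh(out$pvalue)
  }
  rownames(out) <- NULL
  out
}
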