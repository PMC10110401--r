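#' Default ARE motif classes
#'
#' The canonical AU-rich element cluster tiers over the RNA alphabet, from
#' the core pentamer to successively W-flanked (W = A or U) nonamer-and-up
#' patterns. Every class contains the core `AUUUA`.
#'
#' @return Data frame with columns `name` and `pattern`.
#' @export
default_are_classes <- function() {
  data.frame(
    name = c("pentamer", "nonamer", "cluster11", "cluster13", "cluster15"),
    pattern = c("AUUUA", "UUAUUUAUU", "WUAUUUAUW", "WWUAUUUAUWW",
                "WWWUAUUUAUWWW"),
    stringsAsFactors = FALSE)
}

validate_are_classes <- function(classes) {
  stopifnot(is.data.frame(classes), all(c("name", "pattern") %in% names(classes)))
  if (any(!nzchar(classes$pattern))) stop("empty ARE pattern")
  if (any(grepl("[^AUGCW]", classes$pattern)))
    stop("ARE patterns must use the alphabet {A,U,G,C,W}")
  if (any(!grepl("AUUUA", gsub("W", "A", classes$pattern)) &
            !grepl("AUUUA", classes$pattern)))
    stop("every ARE class must contain the core AUUUA")
  classes
}

are_regex <- function(pattern) gsub("W", "[AU]", pattern, fixed = TRUE)

#' Scan sequences for AU-rich element motifs
#'
#' Counts overlapping occurrences of each motif class on the given strand
#' (3'-UTRs are assumed to be in sense orientation already). `N` never
#' matches; any character outside `{A,C,G,U,N}` is an error. The `total`
#' column is the count of the shortest (pentamer) class.
#'
#' @param seqs Named character vector of RNA sequences (as from
#'   [read_sequences()]), or a single unnamed sequence.
#' @param classes Motif classes, default [default_are_classes()].
#' @param positions If `TRUE`, attach an attribute `positions` (per
#'   sequence, per class: 1-based inclusive match starts).
#' @return An ARE profile data frame: `gene`, `utr_length`, one column per
#'   class, and `total`.
#' @export
scan_ares <- function(seqs, classes = default_are_classes(), positions = FALSE) {
  classes <- validate_are_classes(classes)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad))
    stop("sequence(s) contain characters outside {A,C,G,U,N} ",
         "(normalize DNA with read_sequences first): ",
         paste(names(seqs)[bad], collapse = ", "))
  pos_list <- if (positions) stats::setNames(vector("list", length(seqs)), names(seqs))
  counts <- matrix(0L, length(seqs), nrow(classes),
                   dimnames = list(names(seqs), classes$name))
  for (ci in seq_len(nrow(classes))) {
    rex <- paste0("(?=", are_regex(classes$pattern[ci]), ")")
    hits <- gregexpr(rex, seqs, perl = TRUE)
    counts[, ci] <- vapply(hits, function(h) {
      if (h[1] == -1L) 0L else length(h)
    }, integer(1))
    if (positions) {
      for (si in seq_along(seqs)) {
        p <- hits[[si]]
        pos_list[[si]][[classes$name[ci]]] <- if (p[1] == -1L) integer(0) else as.integer(p)
      }
    }
  }
  out <- data.frame(gene = names(seqs), utr_length = nchar(seqs),
                    counts, total = counts[, 1],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (positions) attr(out, "positions") <- pos_list
  out
}

#' Group summaries and pairwise tests of UTR length and ARE count
#'
#' Per label group (`up`, `down`, `nd`): n, median and quartiles of
#' `utr_length` and of the `total` ARE count, plus all pairwise two-sided
#' Wilcoxon rank-sum p-values for each measure. A pair involving an empty
#' group is reported with `p = NA` rather than an error.
#'
#' @param profiles ARE profile data frame from [scan_ares()].
#' @param labels Named character vector `gene -> {"up","down","nd"}`; every
#'   labeled gene must have a profile.
#' @return List with `summary` (per group x measure) and `tests`
#'   (per measure x group pair: `W`, `p`).
#' @export
utr_group_stats <- function(profiles, labels) {
  stopifnot(is.data.frame(profiles), !is.null(names(labels)))
  labels <- labels[!is.na(labels)]
  miss <- setdiff(names(labels), profiles$gene)
  if (length(miss))
    stop("labeled gene(s) without a profile: ",
         paste(utils::head(miss, 5), collapse = ", "))
  bad <- setdiff(unique(labels), c("up", "down", "nd"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  idx <- match(names(labels), profiles$gene)
  dat <- data.frame(group = as.character(labels),
                    utr_length = profiles$utr_length[idx],
                    are_total = profiles$total[idx], stringsAsFactors = FALSE)
  groups <- c("up", "down", "nd")
  measures <- c("utr_length", "are_total")
  summary <- do.call(rbind, lapply(groups, function(g) {
    sub <- dat[dat$group == g, , drop = FALSE]
    do.call(rbind, lapply(measures, function(m) {
      v <- sub[[m]]
      data.frame(group = g, measure = m, n = length(v),
                 q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
                 median = if (length(v)) stats::median(v) else NA_real_,
                 q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(measures, function(m) {
    do.call(rbind, lapply(pairs, function(pr) {
      x <- dat[[m]][dat$group == pr[1]]
      y <- dat[[m]][dat$group == pr[2]]
      if (!length(x) || !length(y)) {
        data.frame(measure = m, group1 = pr[1], group2 = pr[2],
                   W = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
      } else {
        w <- wilcoxon_rank_sum(x, y)
        data.frame(measure = m, group1 = pr[1], group2 = pr[2],
                   W = w$W, p = w$p, stringsAsFactors = FALSE)
      }
    }))
  }))
  rownames(summary) <- rownames(tests) <- NULL
  list(summary = summary, tests = tests)
}

#' Wilcoxon rank-sum test
#'
#' `W` is the rank sum of `x` under midrank ties. The p-value is exact (by
#' enumeration) when the samples are tie-free with `|x| + |y| <= 12`, and a
#' normal approximation with tie and continuity correction otherwise
#' (delegated to [stats::wilcox.test()], which enumerates exactly in the
#' same regime).
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `W` (rank sum of `x`) and two-sided `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x)
  tie_free <- !anyDuplicated(c(x, y))
  exact <- tie_free && (nx + length(y)) <= 12
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  ranks <- rank(c(x, y))
  list(W = sum(ranks[seq_len(nx)]), p = wt$p.value, exact = exact)
}

#' Flag genes with below-average ARE content
#'
#' Flags each gene of `subset` whose total ARE count is strictly below the
#' arithmetic mean of the total ARE count over the whole profile universe.
#'
#' @param subset Character vector of gene ids (must all have profiles).
#' @param profiles ARE profile data frame ([scan_ares()]) defining the
#'   universe.
#' @return List with `flags` (named logical), `n_below`, `fraction`, and
#'   `universe_mean`.
#' @export
below_average_flag <- function(subset, profiles) {
  stopifnot(is.data.frame(profiles))
  if (!nrow(profiles)) stop("empty profile universe")
  miss <- setdiff(subset, profiles$gene)
  if (length(miss))
    stop("subset gene(s) without a profile: ",
         paste(utils::head(miss, 5), collapse = ", "))
  avg <- mean(profiles$total)
  tot <- profiles$total[match(subset, profiles$gene)]
  flags <- setNames(tot < avg, subset)
  list(flags = flags, n_below = sum(flags),
       fraction = if (length(flags)) mean(flags) else NA_real_,
       universe_mean = avg)
}
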