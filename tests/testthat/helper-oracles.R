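# Independent brute-force oracles used to freeze expected values.

# BH step-up, directly from the definition: q_(i) = min_{j>=i} (m/j) p_(j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min((m / i:m) * ps[i:m]))
  out <- numeric(m)
  out[o] <- q
  out
}

# overlapping motif count by explicit sliding window; W = A or U
scan_oracle <- function(seq, pattern) {
  k <- nchar(pattern)
  L <- nchar(seq)
  if (L < k) return(0L)
  pat <- strsplit(pattern, "")[[1]]
  starts <- seq_len(L - k + 1)
  windows <- substring(seq, starts, starts + k - 1)
  hit <- vapply(windows, function(w) {
    wc <- strsplit(w, "")[[1]]
    all(ifelse(pat == "W", wc %in% c("A", "U"), wc == pat))
  }, logical(1), USE.NAMES = FALSE)
  sum(hit)
}

scan_oracle_positions <- function(seq, pattern) {
  k <- nchar(pattern)
  L <- nchar(seq)
  if (L < k) return(integer(0))
  starts <- seq_len(L - k + 1)
  windows <- substring(seq, starts, starts + k - 1)
  rex <- paste0("^", gsub("W", "[AU]", pattern, fixed = TRUE), "$")
  starts[grepl(rex, windows)]
}

# naive UPGMA over a distance matrix: returns sorted merge heights
upgma_heights_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- active[ij[1]]; j <- active[ij[2]]
    heights <- c(heights, d[i, j])
    # average linkage: weighted by cluster sizes
    new_d <- (sizes[i] * d[i, ] + sizes[j] * d[j, ]) / (sizes[i] + sizes[j])
    d[i, ] <- new_d; d[, i] <- new_d
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# exact two-sided rank-sum p by full enumeration of group assignments
wilcox_enum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# upper-tail hypergeometric p by enumerating every possible hit subset
hyper_enum_oracle <- function(overlap, set_size, universe_size, n_hits) {
  idx_set <- seq_len(set_size)
  combos <- utils::combn(universe_size, n_hits)
  ov <- apply(combos, 2, function(s) sum(s %in% idx_set))
  mean(ov >= overlap)
}
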