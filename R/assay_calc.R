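#' RIP-qPCR fold enrichment (2^-dCt)
#'
#' `dCt = mean(Ct_IP) - mean(Ct_IgG)`; fold enrichment `FE = 2^-dCt`, so an
#' IP amplifying earlier than the IgG mock gives FE > 1. (A Ct "ratio"
#' sometimes quoted for this quantity is a difference of cycle thresholds:
#' Ct values are already log2-scale.) The spread is propagated from the
#' replicate standard deviations on the dCt scale.
#'
#' @param ct_ip,ct_igg Replicate Ct values (cycles, each in (0, 50)).
#' @return List with `fold_enrichment`, `delta_ct`, `se` (standard error of
#'   FE by the delta method; `NA` with single replicates), `n_ip`, `n_igg`.
#' @export
fold_enrichment <- function(ct_ip, ct_igg) {
  check_ct(ct_ip, "ct_ip"); check_ct(ct_igg, "ct_igg")
  dct <- mean(ct_ip) - mean(ct_igg)
  fe <- 2^(-dct)
  v <- ct_var(ct_ip) / length(ct_ip) + ct_var(ct_igg) / length(ct_igg)
  list(fold_enrichment = fe, delta_ct = dct,
       se = fe * log(2) * sqrt(v),
       n_ip = length(ct_ip), n_igg = length(ct_igg))
}

#' Relative expression (2^-ddCt)
#'
#' `dCt = Ct_target - Ct_housekeeping` per condition;
#' `ddCt = dCt_treatment - dCt_control`; returns `2^-ddCt`. Exactly
#' invariant to any constant added to every Ct (a common efficiency shift)
#' and to housekeeping shifts common to both conditions.
#'
#' @param ct_target_treat,ct_hk_treat Replicate Cts of target and
#'   housekeeping gene under treatment.
#' @param ct_target_ctrl,ct_hk_ctrl The same under the control condition.
#' @return List with `rel_expression`, `ddct`, `se` (delta method), and the
#'   per-condition `dct` values.
#' @export
relative_expression <- function(ct_target_treat, ct_hk_treat,
                                ct_target_ctrl, ct_hk_ctrl) {
  args <- list(ct_target_treat = ct_target_treat, ct_hk_treat = ct_hk_treat,
               ct_target_ctrl = ct_target_ctrl, ct_hk_ctrl = ct_hk_ctrl)
  for (nm in names(args)) check_ct(args[[nm]], nm)
  dct_t <- mean(ct_target_treat) - mean(ct_hk_treat)
  dct_c <- mean(ct_target_ctrl) - mean(ct_hk_ctrl)
  ddct <- dct_t - dct_c
  re <- 2^(-ddct)
  v <- sum(vapply(args, function(x) ct_var(x) / length(x), numeric(1)))
  list(rel_expression = re, ddct = ddct, se = re * log(2) * sqrt(v),
       dct_treat = dct_t, dct_ctrl = dct_c)
}

check_ct <- function(x, what) {
  if (!length(x)) stop(what, ": needs >= 1 replicate Ct")
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 50))
    stop(what, ": Ct values must lie in (0, 50) cycles")
  invisible(TRUE)
}

ct_var <- function(x) if (length(x) > 1) stats::var(x) else NA_real_

#' Fit a dose-response inhibition curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (x/IC50)^hill)`.
#' In `one_site` mode the Hill slope is fixed at 1 (one-site binding
#' nomenclature); `four_param` frees it. Initialization is multi-start over
#' a log-spaced IC50 grid spanning the tested concentrations
#' (via [minpack.lm::nlsLM]); the best converged fit by residual sum of
#' squares is returned.
#'
#' @param conc Positive concentrations (>= 4 distinct values).
#' @param response Finite responses, same length.
#' @param mode `"one_site"` (default) or `"four_param"`.
#' @return Object of class `dose_response_fit`: list with `ic50`, `top`,
#'   `bottom`, `hill`, `rss`, `fitted`, `converged`, `extrapolated` (IC50
#'   outside the tested span), `mode`.
#' @export
fit_dose_response <- function(conc, response, mode = c("one_site", "four_param")) {
  mode <- match.arg(mode)
  if (length(conc) != length(response)) stop("conc and response lengths differ")
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be positive and finite")
  if (any(!is.finite(response))) stop("responses must be finite")
  if (length(unique(conc)) < 4) stop("need >= 4 distinct concentrations")
  dat <- data.frame(x = conc, y = response)
  ord <- order(dat$x)
  top0 <- mean(dat$y[dat$x == min(dat$x)])
  bot0 <- mean(dat$y[dat$x == max(dat$x)])
  starts <- 10^seq(log10(min(conc)), log10(max(conc)), length.out = 7)
  best <- NULL
  for (s in starts) {
    st <- list(top = top0, bottom = bot0, ic50 = s)
    lower <- c(-Inf, -Inf, min(conc) * 1e-6)
    fml <- y ~ bottom + (top - bottom) / (1 + (x / ic50))
    if (mode == "four_param") {
      st$hill <- 1
      lower <- c(lower, 1e-3)
      fml <- y ~ bottom + (top - bottom) / (1 + (x / ic50)^hill)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    err <- simpleError("dose-response fit did not converge from any start")
    attr(err, "best_attempt") <- list(start_top = top0, start_bottom = bot0,
                                      ic50_grid = starts)
    stop(err)
  }
  cf <- stats::coef(best$fit)
  structure(list(ic50 = unname(cf["ic50"]), top = unname(cf["top"]),
                 bottom = unname(cf["bottom"]),
                 hill = if (mode == "four_param") unname(cf["hill"]) else 1,
                 rss = best$rss, fitted = stats::fitted(best$fit),
                 converged = TRUE,
                 extrapolated = cf["ic50"] < min(conc) || cf["ic50"] > max(conc),
                 mode = mode, model = best$fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose_response_fit [%s]: IC50 = %.4g, top = %.4g, bottom = %.4g, hill = %.3g, RSS = %.4g%s\n",
              x$mode, x$ic50, x$top, x$bottom, x$hill, x$rss,
              if (x$extrapolated) " (IC50 extrapolated)" else ""))
  invisible(x)
}

#' Hook-point of a protein titration
#'
#' The titration maximum: the concentration giving the largest signal.
#' A convenience helper for assay setup, not an estimator.
#'
#' @param conc Concentrations tested.
#' @param signal Signal at each concentration.
#' @return The concentration at the signal maximum.
#' @export
hook_point <- function(conc, signal) {
  stopifnot(length(conc) == length(signal), length(conc) > 0)
  conc[which.max(signal)]
}

#' Welch's t-test
#'
#' Two-sample t-test without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom), two-sided.
#'
#' @param x,y Numeric vectors with >= 2 values each; at least one sample
#'   must have positive variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples have zero variance; the statistic is undefined")
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
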