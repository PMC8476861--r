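#' Cochran's Q heterogeneity test
#'
#' Measures heterogeneity of per-SNP causal estimates around the pooled
#' estimate. With `reference = "ivw"`, `Q = sum(w_j * (r_j - b_ivw)^2)`
#' with ratio estimates `r_j = by/bx` and weights `w_j = bx^2/sy^2`
#' (J - 1 degrees of freedom). With `reference = "egger"`, Q is the
#' weighted residual sum of squares about the fitted Egger line with
#' weights `1/sy^2` (J - 2 degrees of freedom). The p-value is the
#' upper-tail chi-square probability.
#'
#' @param dat harmonized instruments.
#' @param reference `"ivw"` or `"egger"`.
#' @return list with `reference`, `Q`, `df`, `pval` and (for ivw) the
#'   per-SNP contributions, which sum to Q exactly.
#' @export
cochran_q <- function(dat, reference = c("ivw", "egger")) {
  reference <- match.arg(reference)
  if (reference == "ivw") {
    .check_dat(dat, 2, "Cochran's Q (IVW)")
    w <- dat$bx^2 / dat$sy^2
    r <- dat$by / dat$bx
    b <- ivw_point(dat$bx, dat$by, dat$sy)
    contrib <- w * (r - b)^2
    q <- sum(contrib)
    df <- nrow(dat) - 1
    names(contrib) <- dat$snp
  } else {
    .check_dat(dat, 3, "Cochran's Q (Egger)")
    fit <- lm(by ~ bx, data = dat, weights = 1 / dat$sy^2)
    contrib <- (1 / dat$sy^2) * residuals(fit)^2
    q <- sum(contrib)
    df <- nrow(dat) - 2
    names(contrib) <- dat$snp
  }
  list(reference = reference, Q = q, df = df,
       pval = pchisq(q, df, lower.tail = FALSE), contributions = contrib)
}

#' Egger intercept test for directional pleiotropy
#'
#' Returns the intercept of the MR-Egger regression with its standard error
#' and two-sided t (J - 2 df) p-value. An intercept compatible with zero is
#' read as no evidence of directional (average non-zero) pleiotropy.
#'
#' @param dat harmonized instruments (J >= 3, exposure-positive).
#' @return list with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(dat) {
  e <- mr_egger(dat)
  list(intercept = e$extras$intercept, se = e$extras$intercept_se,
       pval = e$extras$intercept_p)
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect omitting each instrument in turn; a
#' single variant whose omission moves the estimate far from the full-set
#' estimate is influential (and a candidate pleiotropic outlier).
#'
#' @param dat harmonized instruments (J >= 3).
#' @param method estimator function taking an instrument data.frame
#'   (default [mr_ivw]).
#' @return data.frame with one row per omitted SNP: `snp_omitted`, `b`,
#'   `se`, `pval`, `ci_low`, `ci_high`.
#' @export
leave_one_out <- function(dat, method = mr_ivw) {
  .check_dat(dat, 3, "leave-one-out")
  rows <- lapply(seq_len(nrow(dat)), function(j) {
    est <- method(dat[-j, , drop = FALSE])
    data.frame(snp_omitted = as.character(dat$snp[j]), b = est$b,
               se = est$se, pval = est$pval, ci_low = est$ci_low,
               ci_high = est$ci_high, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble funnel, scatter, forest and leave-one-out plot data
#'
#' Produces the numeric tables behind the standard MR diagnostic figures
#' (no rendering): the funnel plot of per-SNP ratio estimates against their
#' precision (asymmetry suggests violated assumptions), the scatter of
#' outcome against exposure effects with one regression line per method
#' (slope = causal estimate; only MR-Egger has a non-zero intercept), the
#' forest table of per-SNP ratios with the overall estimates appended, and
#' the leave-one-out series.
#'
#' @param dat harmonized instruments.
#' @param estimates named list of `mr_result` objects (from [mr_all()]).
#' @param loo optional leave-one-out table (from [leave_one_out()]).
#' @return list with elements `funnel`, `scatter_points`, `scatter_lines`,
#'   `forest`, `loo`.
#' @export
assemble_plot_data <- function(dat, estimates, loo = NULL) {
  stopifnot(length(estimates) > 0)
  r <- ratio_estimates(dat)
  funnel <- data.frame(snp = r$snp, ratio = r$ratio,
                       precision = 1 / r$se_ratio, stringsAsFactors = FALSE)
  scatter_points <- data.frame(snp = dat$snp, bx = dat$bx, sx = dat$sx,
                               by = dat$by, sy = dat$sy,
                               stringsAsFactors = FALSE)
  scatter_lines <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(method = e$method,
               intercept = if (!is.null(e$extras$intercept))
                 e$extras$intercept else 0,
               slope = e$b, stringsAsFactors = FALSE)
  }))
  rownames(scatter_lines) <- NULL
  single <- mr_single_snp(dat)
  forest <- rbind(
    data.frame(label = single$snp, b = single$b, ci_low = single$ci_low,
               ci_high = single$ci_high, type = "snp",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(estimates, function(e) {
      data.frame(label = e$method, b = e$b, ci_low = e$ci_low,
                 ci_high = e$ci_high, type = "overall",
                 stringsAsFactors = FALSE)
    }))
  )
  rownames(forest) <- NULL
  list(funnel = funnel, scatter_points = scatter_points,
       scatter_lines = scatter_lines, forest = forest, loo = loo)
}
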