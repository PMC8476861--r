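#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Detects horizontally pleiotropic instruments by comparing observed
#' residuals against a parametric simulation under the no-pleiotropy model.
#'
#' *Global test*: the observed residual sum of squares
#' `RSS = sum((by_j - theta_(-j) * bx_j)^2)`, where `theta_(-j)` is the
#' leave-one-out IVW estimate, is compared with the same statistic computed
#' on `n_sim` simulated datasets drawn under the null
#' (`by_j ~ N(theta_(-j) * bx_j, sy_j)`, `bx_j ~ N(bx_j, sx_j)`); the
#' empirical p-value is `(1 + #(sim >= obs)) / (n_sim + 1)`, so it is never
#' zero and never below `1/(n_sim + 1)`.
#'
#' *Outlier test*: each SNP's observed squared residual is compared with
#' its simulated distribution; per-SNP empirical p-values are
#' Bonferroni-adjusted and SNPs below `outlier_alpha` are flagged.
#'
#' *Distortion test*: the relative difference between the all-SNP and
#' outlier-removed IVW estimates is compared against a bootstrap
#' distribution obtained by resampling non-outlier SNPs.
#'
#' @param dat harmonized instruments (J >= 4; `sx` required).
#' @param n_sim number of null simulations (default 1000).
#' @param seed RNG seed, required (results are reproducible given
#'   `n_sim` and `seed`; the caller's RNG state is untouched).
#' @param outlier_alpha significance level for Bonferroni-adjusted outlier
#'   flags (default 0.05).
#' @param distortion_reps bootstrap resamples for the distortion test.
#' @return object of class `mr_presso`: list with `global_rss`, `global_p`,
#'   `outlier_pvals` (per-SNP, Bonferroni-adjusted alongside raw),
#'   `outliers` (SNP ids), `distortion_p`, `corrected` (outlier-removed IVW
#'   `mr_result`, present iff outliers were found), `n_sim`, `seed`.
#' @export
mr_presso <- function(dat, n_sim = 1000, seed, outlier_alpha = 0.05,
                      distortion_reps = 1000) {
  .check_dat(dat, 4, "MR-PRESSO")
  if (missing(seed) || is.null(seed)) stop("MR-PRESSO requires a seed")
  if (is.null(dat$sx)) stop("MR-PRESSO requires sx")
  J <- nrow(dat)
  bx <- dat$bx; by <- dat$by; sx <- dat$sx; sy <- dat$sy
  w <- 1 / sy^2

  loo_theta <- function(BX, BY) {
    # rows = datasets, cols = SNPs; weights fixed at 1/sy^2
    sxy <- BX * BY * rep(w, each = nrow(BX))
    sxx <- BX^2 * rep(w, each = nrow(BX))
    (rowSums(sxy) - sxy) / (rowSums(sxx) - sxx)
  }

  theta_mj <- drop(loo_theta(matrix(bx, 1), matrix(by, 1)))
  e_obs <- by - theta_mj * bx
  rss_obs <- sum(e_obs^2)

  sims <- with_seed(seed, {
    BX <- matrix(rnorm(n_sim * J, rep(bx, each = n_sim),
                       rep(sx, each = n_sim)), n_sim, J)
    BY <- matrix(rnorm(n_sim * J, rep(theta_mj * bx, each = n_sim),
                       rep(sy, each = n_sim)), n_sim, J)
    E <- BY - loo_theta(BX, BY) * BX
    list(E2 = E^2, rss = rowSums(E^2))
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  raw_p <- (1 + colSums(sims$E2 >= rep(e_obs^2, each = n_sim))) / (n_sim + 1)
  adj_p <- pmin(1, raw_p * J)
  is_outlier <- adj_p < outlier_alpha
  outliers <- as.character(dat$snp[is_outlier])

  corrected <- NULL
  distortion_p <- NA_real_
  if (any(is_outlier)) {
    keep <- which(!is_outlier)
    if (length(keep) < 2) {
      warning("fewer than 2 non-outlier SNPs; no corrected estimate")
    } else {
      corrected <- mr_ivw(dat[keep, , drop = FALSE])
      b_all <- ivw_point(bx, by, sy)
      d_obs <- (b_all - corrected$b) / abs(corrected$b)
      d_boot <- with_seed(seed + 1L, {
        vapply(seq_len(distortion_reps), function(i) {
          idx <- sample(keep, length(keep), replace = TRUE)
          b_ref <- ivw_point(bx[idx], by[idx], sy[idx])
          full <- c(idx, which(is_outlier))
          b_full <- ivw_point(bx[full], by[full], sy[full])
          (b_full - b_ref) / abs(b_ref)
        }, numeric(1))
      })
      distortion_p <- (1 + sum(abs(d_boot) >= abs(d_obs))) /
        (distortion_reps + 1)
    }
  }

  structure(
    list(global_rss = rss_obs, global_p = global_p,
         outlier_pvals = data.frame(snp = as.character(dat$snp),
                                    raw_p = raw_p, adj_p = adj_p,
                                    outlier = is_outlier,
                                    stringsAsFactors = FALSE),
         outliers = outliers, distortion_p = distortion_p,
         corrected = corrected, n_sim = n_sim, seed = seed),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.4g, p = %.4g (n_sim = %d)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (length(x$outliers) > 0) {
    cat("outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$corrected)) {
      cat(sprintf("outlier-corrected IVW: b = %.3f, se = %.3f, p = %.3g\n",
                  x$corrected$b, x$corrected$se, x$corrected$pval))
      cat(sprintf("distortion test p = %.4g\n", x$distortion_p))
    }
  } else {
    cat("no outliers detected\n")
  }
  invisible(x)
}
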