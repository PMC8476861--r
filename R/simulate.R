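#' Simulate two-sample summary statistics with known ground truth
#'
#' Generates exposure and outcome association tables for `J` independent
#' instruments under the structural model of two-sample MR. True exposure
#' effects are latent, `gamma_j ~ N(0, gamma_sd^2)` up to allele labeling:
#' the effect allele is taken to be the exposure-increasing one, so
#' `gamma_j = |N(0, gamma_sd^2)|` in the emitted orientation (allele labels
#' are arbitrary, and fixing them this way makes the direction of planted
#' pleiotropy well defined relative to the orientation the Egger intercept
#' is estimated in). The observed exposure
#' effect adds estimation noise, `bx_j = gamma_j + N(0, sx^2)` (so methods
#' that model exposure-side noise, like RAPS, are distinguishable from
#' those that ignore it). The outcome effect is
#' `by_j = theta * gamma_j + alpha_j + N(0, sy^2)` where the direct
#' (pleiotropic) effect `alpha_j` is:
#'
#' * `"none"`: 0 (exclusion restriction holds);
#' * `"balanced"`: `N(0, alpha_sd^2)` (mean-zero pleiotropy, InSIDE holds);
#' * `"directional"`: `N(alpha_mean, alpha_sd^2)` (non-zero average
#'   pleiotropy, InSIDE holds — the Egger intercept targets `alpha_mean`);
#' * `"inside_violating"`: directional with `alpha_j` correlated 0.5 with
#'   `gamma_j` (instrument strength no longer independent of the direct
#'   effect).
#'
#' `n_outliers` instruments additionally receive a gross pleiotropic effect
#' of `outlier_scale * sy` (planted outliers for testing detection).
#' Alleles are drawn as non-palindromic A/G pairs with effect-allele
#' frequency uniform on (0.1, 0.9), so the data exercise the harmonization
#' step without strand ambiguity. The same `seed` yields bit-identical
#' datasets.
#'
#' Defaults mirror the leptin/anorexia study scale: per-SNP exposure
#' effects of a few hundredths of a unit with GWAS-precision standard
#' errors (`sx = 0.005`) and case-control outcome standard errors on the
#' log-odds scale (`sy = 0.0136`).
#'
#' @param J number of instruments (>= 2).
#' @param theta true causal effect (outcome log-odds per unit exposure).
#' @param gamma_sd SD of the true exposure effects (default 0.03).
#' @param sx,sy per-study standard errors, scalar or length-J.
#' @param pleiotropy one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param alpha_mean,alpha_sd pleiotropy distribution parameters.
#' @param n_outliers number of planted gross outliers (< J).
#' @param outlier_scale outlier pleiotropy as a multiple of `sy`.
#' @param seed RNG seed (required; the caller's RNG state is untouched).
#' @return list with `exposure` and `outcome` (validated association
#'   data.frames sharing SNP ids and alleles) and `truth` (list with
#'   `theta`, `gamma`, `alpha`, `outlier_idx`, `seed`).
#' @export
simulate_summary_stats <- function(J = 50, theta = 0, gamma_sd = 0.03,
                                   sx = 0.005, sy = 0.0136,
                                   pleiotropy = c("none", "balanced",
                                                  "directional",
                                                  "inside_violating"),
                                   alpha_mean = 0, alpha_sd = 0,
                                   n_outliers = 0, outlier_scale = 10,
                                   seed) {
  pleiotropy <- match.arg(pleiotropy)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  stopifnot(J >= 2, all(sx > 0), all(sy > 0), gamma_sd > 0,
            n_outliers >= 0, n_outliers < J)
  sx <- rep(sx, length.out = J)
  sy <- rep(sy, length.out = J)

  with_seed(seed, {
    # Effect alleles are labeled as the exposure-increasing allele, so the
    # true exposure effect is non-negative by construction (allele labels
    # are arbitrary; this fixes the orientation that directional pleiotropy
    # and the Egger intercept are defined relative to).
    gamma <- abs(rnorm(J, 0, gamma_sd))
    gamma_std <- (gamma - mean(gamma)) / sd(gamma)
    alpha <- switch(pleiotropy,
      none = rep(0, J),
      balanced = rnorm(J, 0, alpha_sd),
      directional = rnorm(J, alpha_mean, alpha_sd),
      inside_violating = alpha_mean + alpha_sd *
        (0.5 * gamma_std + sqrt(0.75) * rnorm(J))
    )
    outlier_idx <- if (n_outliers > 0) sample.int(J, n_outliers) else integer(0)
    alpha[outlier_idx] <- alpha[outlier_idx] + outlier_scale * sy[outlier_idx]

    bx <- gamma + rnorm(J, 0, sx)
    by <- theta * gamma + alpha + rnorm(J, 0, sy)
    eaf <- runif(J, 0.1, 0.9)
    snp <- sprintf("sim%03d", seq_len(J))

    exposure <- data.frame(
      snp = snp, chr = "1", pos = seq_len(J) * 1e6, ea = "A", oa = "G",
      eaf = eaf, beta = bx, se = sx,
      pval = pmax(2 * pnorm(-abs(bx / sx)), 1e-300), n = NA_real_,
      trait = "sim_exposure", stringsAsFactors = FALSE)
    outcome <- data.frame(
      snp = snp, chr = "1", pos = seq_len(J) * 1e6, ea = "A", oa = "G",
      eaf = eaf, beta = by, se = sy,
      pval = pmax(2 * pnorm(-abs(by / sy)), 1e-300), n = NA_real_,
      trait = "sim_outcome", stringsAsFactors = FALSE)

    list(exposure = validate_sumstats(exposure),
         outcome = validate_sumstats(outcome),
         truth = list(theta = theta, gamma = gamma, alpha = alpha,
                      outlier_idx = sort(outlier_idx), seed = seed))
  })
}
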