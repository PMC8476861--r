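# Causal-effect estimators for two-sample MR. All take a data.frame of
# harmonized instruments (columns snp, bx, sx, by, sy) and return an
# "mr_result". Every estimator is invariant to a joint sign flip of any
# instrument's (bx, by); MR-Egger additionally requires the
# exposure-positive orientation produced by harmonize().

Z95 <- 1.96  # CIs are always b +/- 1.96 * se, matching reported bounds

mr_result <- function(method, b, se, pval, n_snp, df = NA_integer_,
                      extras = list()) {
  stopifnot(is.finite(b), is.finite(se), se > 0)
  structure(
    list(method = method, b = b, se = se, pval = pval,
         ci_low = b - Z95 * se, ci_high = b + Z95 * se,
         n_snp = n_snp, df = df, extras = extras),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: b = %.3f, se = %.3f, p = %.3g, 95%% CI [%.3f, %.3f], n_snp = %d\n",
              x$method, x$b, x$se, x$pval, x$ci_low, x$ci_high, x$n_snp))
  if (!is.null(x$extras$intercept)) {
    cat(sprintf("  intercept = %.3f, se = %.3f, p = %.3g\n",
                x$extras$intercept, x$extras$intercept_se,
                x$extras$intercept_p))
  }
  invisible(x)
}

#' Collect MR results into a table
#'
#' @param results list of `mr_result` objects.
#' @return data.frame with columns `method`, `b`, `se`, `pval`, `ci_low`,
#'   `ci_high`, `n_snp`, mirroring the layout of published MR result tables.
#' @export
mr_result_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, b = r$b, se = r$se, pval = r$pval,
               ci_low = r$ci_low, ci_high = r$ci_high, n_snp = r$n_snp,
               stringsAsFactors = FALSE)
  }))
}

.check_dat <- function(dat, min_snp, method) {
  stopifnot(all(c("bx", "by", "sy") %in% names(dat)))
  if (nrow(dat) < min_snp) {
    stop(method, " requires at least ", min_snp, " instruments, got ",
         nrow(dat))
  }
  if (any(dat$sy <= 0)) stop("sy must be positive")
  invisible(dat)
}

# Run code under a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Per-SNP ratio estimates, first-order SEs, and inverse-variance weights.
ratio_estimates <- function(dat) {
  if (any(dat$bx == 0)) stop("ratio estimate undefined for bx = 0")
  data.frame(snp = if (!is.null(dat$snp)) dat$snp else seq_len(nrow(dat)),
             ratio = dat$by / dat$bx,
             se_ratio = dat$sy / abs(dat$bx),
             weight = dat$bx^2 / dat$sy^2,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimate from a single instrument
#'
#' The per-variant causal estimate `by/bx` with first-order delta-method
#' standard error `sy/|bx|`; two-sided normal p-value.
#'
#' @param dat one-row harmonized-instrument data.frame.
#' @return `mr_result`.
#' @export
mr_wald_ratio <- function(dat) {
  .check_dat(dat, 1, "Wald ratio")
  dat <- dat[1, , drop = FALSE]
  if (dat$bx == 0) stop("Wald ratio undefined for bx = 0")
  b <- dat$by / dat$bx
  se <- dat$sy / abs(dat$bx)
  mr_result("Wald ratio", b, se, 2 * pnorm(-abs(b / se)), 1,
            extras = list(snp = as.character(dat$snp)))
}

#' Per-SNP Wald ratio table
#'
#' @param dat harmonized instruments.
#' @return data.frame with one row per SNP: `snp`, `b`, `se`, `pval`,
#'   `ci_low`, `ci_high`.
#' @export
mr_single_snp <- function(dat) {
  r <- ratio_estimates(dat)
  data.frame(snp = r$snp, b = r$ratio, se = r$se_ratio,
             pval = 2 * pnorm(-abs(r$ratio / r$se_ratio)),
             ci_low = r$ratio - Z95 * r$se_ratio,
             ci_high = r$ratio + Z95 * r$se_ratio,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' Combines per-SNP ratio estimates with inverse-variance weights
#' `bx^2/sy^2`; the point estimate equals weighted least squares of `by` on
#' `bx` through the origin with weights `1/sy^2`. The variance model is
#' multiplicative random effects with the residual scale floored at one:
#' `se = max(1, sqrt(Q/(J-1))) / sqrt(sum(bx^2/sy^2))`, so under
#' homogeneity (Q/df <= 1) the fixed-effect standard error is reported
#' unchanged. Two-sided normal p-value.
#'
#' @param dat harmonized instruments (J >= 2; use [mr_wald_ratio()] for a
#'   single instrument).
#' @return `mr_result`; `extras$sigma` holds the residual scale
#'   `sqrt(Q/(J-1))` before flooring.
#' @export
mr_ivw <- function(dat) {
  .check_dat(dat, 2, "IVW")
  w <- 1 / dat$sy^2
  sxx <- sum(dat$bx^2 * w)
  b <- sum(dat$bx * dat$by * w) / sxx
  se_fixed <- 1 / sqrt(sxx)
  J <- nrow(dat)
  q <- sum(w * (dat$by - b * dat$bx)^2)
  sigma <- sqrt(q / (J - 1))
  se <- se_fixed * max(1, sigma)
  mr_result("Inverse variance weighted", b, se, 2 * pnorm(-abs(b / se)), J,
            df = J - 1,
            extras = list(sigma = sigma, se_fixed = se_fixed, Q = q))
}

# IVW point estimate only (fast path used by leave-one-out and PRESSO).
ivw_point <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(bx * by * w) / sum(bx^2 * w)
}

#' MR-Egger regression
#'
#' Weighted least squares of `by` on `bx` with an intercept and weights
#' `1/sy^2`. The slope is the causal estimate under the InSIDE assumption;
#' the intercept estimates the average directional pleiotropic effect (a
#' value compatible with zero is taken as no evidence of directional
#' pleiotropy). Both standard errors are scaled by the residual standard
#' deviation floored at one; p-values are two-sided from a t distribution
#' with J - 2 degrees of freedom. Requires the exposure-positive
#' orientation (all `bx > 0`).
#'
#' @param dat harmonized instruments (J >= 3).
#' @return `mr_result` with `extras$intercept`, `extras$intercept_se`,
#'   `extras$intercept_p`.
#' @export
mr_egger <- function(dat) {
  .check_dat(dat, 3, "MR-Egger")
  if (any(dat$bx <= 0)) {
    stop("MR-Egger requires exposure-positive orientation (all bx > 0); ",
         "harmonize with exposure_positive = TRUE")
  }
  J <- nrow(dat)
  fit <- lm(by ~ bx, data = dat, weights = 1 / dat$sy^2)
  s <- summary(fit)
  scale_up <- max(1, s$sigma) / s$sigma
  slope <- coef(fit)[["bx"]]
  slope_se <- s$coefficients["bx", "Std. Error"] * scale_up
  a <- coef(fit)[["(Intercept)"]]
  a_se <- s$coefficients["(Intercept)", "Std. Error"] * scale_up
  mr_result("MR Egger", slope, slope_se,
            2 * pt(-abs(slope / slope_se), df = J - 2), J, df = J - 2,
            extras = list(intercept = a, intercept_se = a_se,
                          intercept_p = 2 * pt(-abs(a / a_se), df = J - 2),
                          residual_sd = s$sigma))
}

# Weighted 50th percentile with linear interpolation over standardized
# cumulative weights p_j = (cumsum(w) - w_j/2) / sum(w).
weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  approx(p, r, xout = 0.5, ties = "ordered")$y
}

median_point <- function(bx, by, sy, kind, penalty = 20) {
  r <- by / bx
  w <- switch(kind,
              simple = rep(1, length(r)),
              weighted = bx^2 / sy^2,
              penalised = bx^2 / sy^2)
  if (kind == "penalised") {
    b_wm <- weighted_median(r, w)
    qj <- pchisq(w * (r - b_wm)^2, df = 1, lower.tail = FALSE)
    w <- w * pmin(1, penalty * qj)
  }
  weighted_median(r, w)
}

#' Median-based causal estimators
#'
#' The weighted 50th percentile of the per-SNP ratio estimates, consistent
#' when up to half of the weight comes from invalid instruments. Kinds:
#' `"simple"` (equal weights), `"weighted"` (inverse-variance weights
#' `bx^2/sy^2`), and `"penalised"` (weighted, with each SNP's weight
#' down-weighted by `min(1, 20 * q_j)` where `q_j` is the upper-tail
#' chi-square(1) probability of its heterogeneity contribution; more robust
#' when instruments are heterogeneous). The standard error comes from a
#' parametric bootstrap that redraws `by ~ N(by, sy)` and `bx ~ N(bx, sx)`.
#'
#' @param dat harmonized instruments (J >= 3; `sx` required).
#' @param kind `"simple"`, `"weighted"` or `"penalised"`.
#' @param boot_reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; recorded in `extras`. The
#'   caller's RNG state is left untouched.
#' @return `mr_result`.
#' @export
mr_median <- function(dat, kind = c("weighted", "simple", "penalised"),
                      boot_reps = 1000, seed = NULL) {
  kind <- match.arg(kind)
  .check_dat(dat, 3, "median estimator")
  b <- median_point(dat$bx, dat$by, dat$sy, kind)
  boots <- with_seed(seed, {
    vapply(seq_len(boot_reps), function(i) {
      by_s <- rnorm(nrow(dat), dat$by, dat$sy)
      bx_s <- rnorm(nrow(dat), dat$bx, dat$sx)
      median_point(bx_s, by_s, dat$sy, kind)
    }, numeric(1))
  })
  se <- sd(boots)
  label <- c(simple = "Simple median", weighted = "Weighted median",
             penalised = "Penalised weighted median")[[kind]]
  mr_result(label, b, se, 2 * pnorm(-abs(b / se)), nrow(dat),
            extras = list(boot_reps = boot_reps, seed = seed))
}

mode_point <- function(bx, by, sy, weighted, phi = 1) {
  r <- by / bx
  w <- if (weighted) bx^2 / sy^2 else rep(1, length(r))
  s <- sd(r)
  m <- mad(r)  # scaled MAD, = raw median absolute deviation / 0.6745
  h <- phi * 0.9 * min(s, m) * length(r)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(r[1])  # all ratios identical
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(g) sum(w * dnorm((g - r) / h)), numeric(1))
  top <- which(dens == max(dens))
  if (length(top) > 1) top <- top[which.min(abs(grid[top]))]
  grid[top]
}

#' Mode-based causal estimators
#'
#' The mode of a normal-kernel density over the per-SNP ratio estimates,
#' consistent under the zero-modal pleiotropy assumption (the most common
#' pleiotropy value across instruments is zero). Weights are equal
#' (`weighted = FALSE`) or inverse-variance `bx^2/sy^2`. The bandwidth is
#' `phi * 0.9 * min(sd, mad) * J^(-1/5)` computed on the ratio estimates
#' (`mad` being the scaled median absolute deviation); the estimate is the
#' density argmax on a 512-point grid spanning the ratios plus three
#' bandwidths, ties broken toward the smaller magnitude. Bootstrap SE as in
#' [mr_median()].
#'
#' @param dat harmonized instruments (J >= 3; `sx` required).
#' @param weighted use inverse-variance weights.
#' @param phi bandwidth multiplier (default 1).
#' @param boot_reps,seed parametric-bootstrap settings.
#' @return `mr_result`.
#' @export
mr_mode <- function(dat, weighted = TRUE, phi = 1, boot_reps = 1000,
                    seed = NULL) {
  .check_dat(dat, 3, "mode estimator")
  b <- mode_point(dat$bx, dat$by, dat$sy, weighted, phi)
  boots <- with_seed(seed, {
    vapply(seq_len(boot_reps), function(i) {
      by_s <- rnorm(nrow(dat), dat$by, dat$sy)
      bx_s <- rnorm(nrow(dat), dat$bx, dat$sx)
      mode_point(bx_s, by_s, dat$sy, weighted, phi)
    }, numeric(1))
  })
  se <- sd(boots)
  label <- if (weighted) "Weighted mode" else "Simple mode"
  mr_result(label, b, se, 2 * pnorm(-abs(b / se)), nrow(dat),
            extras = list(phi = phi, boot_reps = boot_reps, seed = seed))
}

# Huber psi and E[Z * psi_k(Z)] under a standard normal.
huber_psi <- function(t, k = 1.345) pmax(-k, pmin(k, t))
huber_delta <- function(k = 1.345) {
  (2 * pnorm(k) - 1) - 2 * k * dnorm(k) + 2 * k^2 * (1 - pnorm(k))
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Solves the profile score equation
#' `sum(bx * psi((by - theta*bx)/sigma_j) / sigma_j) = 0` with
#' `sigma_j^2 = sy^2 + theta^2 * sx^2 + tau^2`, accounting for measurement
#' error in the exposure effects (unlike IVW) and, with
#' `overdispersion = TRUE`, estimating a systematic-pleiotropy variance
#' `tau^2 >= 0` jointly from the second-moment equation. `loss = "l2"` uses
#' the identity score; `loss = "huber"` bounds the influence of instruments
#' with large standardized residuals (idiosyncratic pleiotropy). Standard
#' error from the profile information `1/sqrt(sum(bx^2/sigma_j^2))`
#' (scaled for the Huber score); two-sided normal p-value.
#'
#' @param dat harmonized instruments (J >= 3; `sx` required and positive).
#' @param overdispersion estimate `tau^2` (default TRUE).
#' @param loss `"l2"` or `"huber"`.
#' @param k Huber tuning constant (default 1.345).
#' @param max_iter,tol convergence controls; non-convergence is an error,
#'   never silent.
#' @return `mr_result` with `extras$tau2` and `extras$iterations`.
#' @export
mr_raps <- function(dat, overdispersion = TRUE, loss = c("l2", "huber"),
                    k = 1.345, max_iter = 100, tol = 1e-10) {
  loss <- match.arg(loss)
  .check_dat(dat, 3, "MR-RAPS")
  if (is.null(dat$sx) || any(!is.finite(dat$sx)) || any(dat$sx < 0)) {
    stop("MR-RAPS requires non-negative sx for all instruments")
  }
  bx <- dat$bx; by <- dat$by; sx <- dat$sx; sy <- dat$sy
  delta <- if (loss == "huber") huber_delta(k) else 1

  score <- function(theta, tau2) {
    sig2 <- sy^2 + theta^2 * sx^2 + tau2
    t <- (by - theta * bx) / sqrt(sig2)
    psi <- if (loss == "huber") huber_psi(t, k) else t
    sum(bx * psi / sqrt(sig2))
  }
  solve_theta <- function(tau2) {
    lo <- -10; hi <- 10
    while (score(lo, tau2) * score(hi, tau2) > 0 && hi < 1e6) {
      lo <- lo * 10; hi <- hi * 10
    }
    uniroot(score, c(lo, hi), tau2 = tau2, tol = 1e-12)$root
  }
  tau2_moment <- function(theta, tau2) {
    # standardized squared residuals should average delta at the truth
    sig2 <- sy^2 + theta^2 * sx^2 + tau2
    t <- (by - theta * bx) / sqrt(sig2)
    psi <- if (loss == "huber") huber_psi(t, k) else t
    sum((t * psi - delta) / sig2)
  }

  tau2 <- 0
  theta <- solve_theta(tau2)
  iter <- 0
  if (overdispersion) {
    repeat {
      iter <- iter + 1
      if (iter > max_iter) stop("MR-RAPS did not converge in ", max_iter,
                                " iterations")
      if (tau2_moment(theta, 0) <= 0) {
        tau2_new <- 0  # residuals underdispersed: boundary estimate
      } else {
        upper <- max(sy^2) * 100 + 1
        tau2_new <- uniroot(function(t2) tau2_moment(theta, t2),
                            c(0, upper), tol = 1e-14)$root
      }
      theta_new <- solve_theta(tau2_new)
      done <- abs(theta_new - theta) < tol && abs(tau2_new - tau2) < tol
      theta <- theta_new
      tau2 <- tau2_new
      if (done) break
    }
  }
  sig2 <- sy^2 + theta^2 * sx^2 + tau2
  info <- sum(bx^2 / sig2)
  se <- if (loss == "huber") sqrt(huber_varfac(k)) / sqrt(info) else
    1 / sqrt(info)
  mr_result("MR RAPS", theta, se, 2 * pnorm(-abs(theta / se)), nrow(dat),
            extras = list(tau2 = tau2, overdispersion = overdispersion,
                          loss = loss, iterations = iter))
}

# Asymptotic variance inflation of the Huber score relative to l2:
# E[psi_k(Z)^2] / (E[psi_k'(Z)])^2 under a standard normal.
huber_varfac <- function(k = 1.345) {
  e_psi2 <- (2 * pnorm(k) - 1) - 2 * k * dnorm(k) + 2 * k^2 * (1 - pnorm(k))
  e_dpsi <- 2 * pnorm(k) - 1
  e_psi2 / e_dpsi^2
}

#' Run the full estimator suite
#'
#' Applies every configured estimator to the instrument set, skipping (with
#' a warning) estimators whose preconditions the data do not meet, and
#' falling back to the Wald ratio when only one instrument remains.
#'
#' @param dat harmonized instruments.
#' @param methods character vector among `"ivw"`, `"egger"`,
#'   `"simple_median"`, `"weighted_median"`, `"penalised_median"`,
#'   `"simple_mode"`, `"weighted_mode"`, `"raps"`, or `"all"`.
#' @param boot_reps,seed bootstrap settings passed to median/mode
#'   estimators (each gets a distinct seed derived from `seed`).
#' @return named list of `mr_result` objects.
#' @export
mr_all <- function(dat, methods = "all", boot_reps = 1000, seed = NULL) {
  all_methods <- c("egger", "ivw", "simple_median", "weighted_median",
                   "penalised_median", "simple_mode", "weighted_mode",
                   "raps")
  if (identical(methods, "all")) methods <- all_methods
  stopifnot(all(methods %in% all_methods))
  if (nrow(dat) == 1) {
    warning("single instrument: reporting the Wald ratio only")
    return(list(wald = mr_wald_ratio(dat)))
  }
  sub_seed <- function(i) if (is.null(seed)) NULL else seed + i
  runners <- list(
    egger = function() mr_egger(dat),
    ivw = function() mr_ivw(dat),
    simple_median = function() mr_median(dat, "simple", boot_reps,
                                         sub_seed(1)),
    weighted_median = function() mr_median(dat, "weighted", boot_reps,
                                           sub_seed(2)),
    penalised_median = function() mr_median(dat, "penalised", boot_reps,
                                            sub_seed(3)),
    simple_mode = function() mr_mode(dat, weighted = FALSE,
                                     boot_reps = boot_reps,
                                     seed = sub_seed(4)),
    weighted_mode = function() mr_mode(dat, weighted = TRUE,
                                       boot_reps = boot_reps,
                                       seed = sub_seed(5)),
    raps = function() mr_raps(dat)
  )
  out <- list()
  for (m in methods) {
    res <- tryCatch(runners[[m]](), error = function(e) {
      warning("estimator '", m, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[m]] <- res
  }
  out
}
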