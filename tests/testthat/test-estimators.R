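test_that("Wald ratio matches the delta-method formula and fixtures", {
  dat <- gwas5()
  lep <- dat[dat$snp == "rs10487505", ]
  est <- mr_wald_ratio(lep)
  # printed -1.387 / 0.587 from unrounded inputs; 2-sf inputs give -1.391
  expect_equal(est$b, -0.032 / 0.023)
  expect_equal(est$se, 0.0135 / 0.023)
  expect_equal(round(est$se, 3), 0.587)

  # null outcome effect
  est0 <- mr_wald_ratio(make_instruments(0.02, 0, 0.01))
  expect_equal(est0$b, 0)
  expect_equal(est0$pval, 1)

  # joint sign flip leaves the estimate unchanged
  flip <- lep
  flip$bx <- -flip$bx
  flip$by <- -flip$by
  est2 <- mr_wald_ratio(flip)
  expect_equal(est2$b, est$b)
  expect_equal(est2$se, est$se)

  expect_error(mr_wald_ratio(make_instruments(0, 0.01, 0.01)), "bx = 0")
})

test_that("IVW equals the weighted-least-squares-through-origin oracle", {
  # independent oracle: lm() through the origin with weights 1/sy^2
  set.seed(401)
  for (i in 1:20) {
    J <- sample(3:30, 1)
    dat <- make_instruments(bx = rnorm(J, 0.05, 0.02),
                            by = rnorm(J, 0, 0.05),
                            sy = runif(J, 0.005, 0.05))
    est <- mr_ivw(dat)
    oracle <- unname(coef(lm(by ~ 0 + bx, data = dat,
                             weights = 1 / dat$sy^2)))
    expect_equal(est$b, oracle, tolerance = 1e-12)
    # fixed-effect SE is exactly 1/sqrt(sum(bx^2/sy^2))
    expect_equal(est$extras$se_fixed, 1 / sqrt(sum(dat$bx^2 / dat$sy^2)),
                 tolerance = 1e-14)
  }
})

test_that("IVW reproduces the leptin GWAS estimates with the floored
           multiplicative random-effects scale", {
  est4 <- mr_ivw(gwas4())
  # homogeneous 4-SNP set: residual scale < 1, fixed-effect SE reported
  expect_lt(est4$extras$sigma, 1)
  expect_equal(est4$b, -0.923, tolerance = 0.01)
  expect_equal(round(est4$se, 3), 0.244)

  est5 <- mr_ivw(gwas5())
  # heterogeneous 5-SNP set: residual scale > 1 inflates the SE
  expect_gt(est5$extras$sigma, 1)
  expect_equal(est5$b, -0.546, tolerance = 0.015)
  expect_equal(est5$se, 0.369, tolerance = 0.002)

  # duplicated instrument: estimate equals the common Wald ratio
  dup <- make_instruments(c(0.02, 0.02), c(-0.03, -0.03), c(0.01, 0.01))
  expect_equal(mr_ivw(dup)$b, -1.5)

  expect_error(mr_ivw(gwas4()[1, ]), "at least 2")
})

test_that("MR-Egger separates slope and average pleiotropy", {
  est <- mr_egger(gwas4())
  expect_equal(est$extras$intercept, -0.057, tolerance = 0.02)
  expect_equal(est$extras$intercept_p, 0.421, tolerance = 0.02)
  expect_equal(est$b, 1.078, tolerance = 0.05)

  # collinear points through the origin: zero intercept, slope exact
  line <- make_instruments(bx = c(0.01, 0.02, 0.03),
                           by = c(0.005, 0.010, 0.015),
                           sy = rep(0.01, 3))
  # lm() warns that the fit is exact; that is the point of the case
  estl <- suppressWarnings(mr_egger(line))
  expect_equal(estl$extras$intercept, 0, tolerance = 1e-12)
  expect_equal(estl$b, 0.5, tolerance = 1e-12)

  # when the fitted intercept is (numerically) zero the slope equals IVW
  # construct data whose weighted Egger intercept vanishes exactly:
  set.seed(402)
  dat <- make_instruments(bx = runif(6, 0.01, 0.05),
                          by = rnorm(6, 0, 0.02), sy = runif(6, 0.01, 0.02))
  fit <- lm(by ~ bx, data = dat, weights = 1 / dat$sy^2)
  dat$by <- dat$by - coef(fit)[1]  # remove the intercept component
  este <- mr_egger(dat)
  expect_equal(este$extras$intercept, 0, tolerance = 1e-10)
  expect_equal(este$b, mr_ivw(dat)$b, tolerance = 1e-8)

  expect_error(mr_egger(gwas4()[1:2, ]), "at least 3")
  neg <- gwas4()
  neg$bx[1] <- -neg$bx[1]
  expect_error(mr_egger(neg), "exposure-positive")
})

test_that("median estimators interpolate weighted ratio quantiles", {
  # equal weights, odd J: the middle order statistic
  odd <- make_instruments(bx = rep(0.02, 5),
                          by = 0.02 * c(-1, 0.2, 0.5, 1, 2),
                          sy = rep(0.01, 5))
  est <- mr_median(odd, "simple", boot_reps = 50, seed = 1)
  expect_equal(est$b, 0.5)

  # weighted median with equal weights equals the simple median
  eq <- make_instruments(bx = rep(0.02, 4), by = rnorm(4, 0, 0.02),
                         sy = rep(0.01, 4))
  expect_equal(mr_median(eq, "weighted", boot_reps = 10, seed = 1)$b,
               mr_median(eq, "simple", boot_reps = 10, seed = 1)$b)

  # all ratios identical -> the common value
  same <- make_instruments(bx = c(0.01, 0.02, 0.04),
                           by = -0.8 * c(0.01, 0.02, 0.04),
                           sy = rep(0.01, 3))
  expect_equal(mr_median(same, "weighted", boot_reps = 10, seed = 1)$b, -0.8)

  # penalised equals weighted when nothing is penalised (homogeneous set)
  expect_equal(mr_median(same, "penalised", boot_reps = 10, seed = 1)$b,
               mr_median(same, "weighted", boot_reps = 10, seed = 1)$b)

  # leptin GWAS 4-SNP set: printed -0.790 from unrounded inputs
  wm <- mr_median(gwas4(), "weighted", boot_reps = 200, seed = 5)
  expect_true(wm$b > -0.82 && wm$b < -0.78)

  expect_error(mr_median(eq[1:2, ], "simple"), "at least 3")
})

test_that("mode estimators find the dominant ratio cluster", {
  # all ratios identical
  same <- make_instruments(bx = c(0.01, 0.02, 0.04),
                           by = 0.3 * c(0.01, 0.02, 0.04),
                           sy = rep(0.01, 3))
  expect_equal(mr_mode(same, boot_reps = 10, seed = 1)$b, 0.3)

  # two separated clusters: estimate lands in the heavier one
  # (verified by brute-force density evaluation at construction)
  cl <- make_instruments(
    bx = rep(0.05, 7),
    by = 0.05 * c(0.98, 1.00, 1.02, 1.01, -0.52, -0.50, -0.48),
    sy = c(rep(0.01, 4), rep(0.03, 3)))
  est <- mr_mode(cl, weighted = TRUE, boot_reps = 10, seed = 1)
  expect_gt(est$b, 0.9)
  expect_lt(est$b, 1.1)

  # leptin GWAS 4-SNP set: printed -0.761 (weighted), -0.782 (simple)
  wmode <- mr_mode(gwas4(), weighted = TRUE, boot_reps = 200, seed = 5)
  expect_equal(wmode$b, -0.761, tolerance = 0.02)
  smode <- mr_mode(gwas4(), weighted = FALSE, boot_reps = 200, seed = 5)
  expect_equal(smode$b, -0.782, tolerance = 0.02)

  expect_error(mr_mode(same[1:2, ]), "at least 3")
})

test_that("RAPS solves the profile score and handles overdispersion", {
  # with sx -> 0 and overdispersion off, RAPS reduces to fixed-effect IVW
  dat <- gwas4()
  dat$sx <- rep(1e-12, 4)
  est <- mr_raps(dat, overdispersion = FALSE)
  expect_equal(est$b, mr_ivw(dat)$b, tolerance = 1e-6)

  # leptin GWAS 4-SNP set: printed -0.930
  est4 <- mr_raps(gwas4())
  expect_equal(est4$b, -0.930, tolerance = 0.02)

  # the returned estimate solves the score equation
  d <- gwas4()
  sig2 <- d$sy^2 + est4$b^2 * d$sx^2 + est4$extras$tau2
  expect_equal(sum(d$bx * (d$by - est4$b * d$bx) / sig2), 0,
               tolerance = 1e-6)

  # unbiased on simulated null data (theta = 0, no pleiotropy)
  ests <- vapply(1:200, function(i) {
    sim <- simulate_summary_stats(J = 30, theta = 0, seed = 5000 + i)
    dat <- harmonize(sim$exposure, sim$outcome)
    mr_raps(dat)$b
  }, numeric(1))
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(200))

  # huber loss gives a finite nearby estimate
  esth <- mr_raps(gwas4(), loss = "huber")
  expect_equal(esth$b, est4$b, tolerance = 0.1)

  bad <- gwas4()
  bad$sx <- NULL
  expect_error(mr_raps(bad), "sx")
})

test_that("all estimators are invariant to joint sign flips and bootstrap
           SEs are reproducible", {
  dat <- gwas4()
  flip <- dat
  flip$bx[2] <- -flip$bx[2]
  flip$by[2] <- -flip$by[2]

  expect_equal(mr_ivw(flip)$b, mr_ivw(dat)$b)
  expect_equal(mr_ivw(flip)$se, mr_ivw(dat)$se)
  expect_equal(mr_raps(flip)$b, mr_raps(dat)$b, tolerance = 1e-9)
  expect_equal(mr_median(flip, "weighted", boot_reps = 10, seed = 3)$b,
               mr_median(dat, "weighted", boot_reps = 10, seed = 3)$b)
  expect_equal(mr_mode(flip, boot_reps = 10, seed = 3)$b,
               mr_mode(dat, boot_reps = 10, seed = 3)$b)
  # egger requires re-orienting, which harmonize would do; the flipped set
  # violates its precondition by construction
  expect_error(mr_egger(flip), "exposure-positive")

  # bit-reproducible bootstrap given (boot_reps, seed), RNG state untouched
  set.seed(999)
  before <- .Random.seed
  a <- mr_median(dat, "weighted", boot_reps = 100, seed = 42)
  expect_identical(before, .Random.seed)
  b <- mr_median(dat, "weighted", boot_reps = 100, seed = 42)
  expect_identical(a$se, b$se)
  m1 <- mr_mode(dat, boot_reps = 100, seed = 42)
  m2 <- mr_mode(dat, boot_reps = 100, seed = 42)
  expect_identical(m1$se, m2$se)
})

test_that("Egger recovers the causal slope under balanced pleiotropy with
           InSIDE, while weighted median beats IVW under 40% invalid
           instruments", {
  theta <- 0.5
  # balanced pleiotropy, InSIDE satisfied
  egger_b <- vapply(1:150, function(i) {
    sim <- simulate_summary_stats(J = 50, theta = theta, gamma_sd = 0.05,
                                  sx = 0.002,
                                  pleiotropy = "balanced", alpha_sd = 0.01,
                                  seed = 7000 + i)
    dat <- harmonize(sim$exposure, sim$outcome)
    mr_egger(dat)$b
  }, numeric(1))
  expect_lt(abs(mean(egger_b) - theta), 3 * sd(egger_b) / sqrt(150))

  # 40% of instruments carry a shared directional pleiotropic effect
  res <- vapply(1:150, function(i) {
    sim <- simulate_summary_stats(J = 20, theta = theta, gamma_sd = 0.05,
                                  n_outliers = 8, outlier_scale = 3,
                                  seed = 8000 + i)
    dat <- harmonize(sim$exposure, sim$outcome)
    c(ivw = mr_ivw(dat)$b,
      wm = mr_median(dat, "weighted", boot_reps = 2, seed = 1)$b)
  }, numeric(2))
  bias_ivw <- abs(mean(res["ivw", ]) - theta)
  bias_wm <- abs(mean(res["wm", ]) - theta)
  expect_lt(bias_wm, bias_ivw)
})
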