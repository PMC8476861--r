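#' Statistical power of a two-sample MR analysis with a binary outcome
#'
#' Normal-approximation power for detecting an odds ratio `or_alt` per unit
#' of exposure, given the outcome study size `n_total`, case fraction `K`,
#' and the fraction `r2` of exposure variance explained by the instruments.
#' The non-centrality is `z = |ln(or_alt)| * sqrt(n_total * r2 * K * (1 - K))`
#' and the two-sided power is
#' `pnorm(z - z_crit) + pnorm(-z - z_crit)` with
#' `z_crit = qnorm(1 - alpha/2)`. At `or_alt = 1` the power equals `alpha`.
#'
#' @param n_total total outcome-study sample size.
#' @param case_fraction proportion of cases, in (0, 1).
#' @param r2 exposure variance explained by the instruments, in \[0, 1\].
#' @param or_alt alternative odds ratio (> 0); direction does not matter.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in \[0, 1\].
#' @export
#' @examples
#' mr_power_binary(72517, 16992 / 72517, 0.097, 1.08)
mr_power_binary <- function(n_total, case_fraction, r2, or_alt,
                            alpha = 0.05) {
  stopifnot(n_total > 0, case_fraction > 0, case_fraction < 1,
            r2 >= 0, r2 <= 1, or_alt > 0, alpha > 0, alpha < 1)
  z <- abs(log(or_alt)) *
    sqrt(n_total * r2 * case_fraction * (1 - case_fraction))
  crit <- qnorm(1 - alpha / 2)
  pnorm(z - crit) + pnorm(-z - crit)
}

#' Drop instruments whose exposure association is not robust to BMI
#'
#' For leptin-like exposures that correlate strongly with adiposity, an
#' instrument acting on the exposure only through BMI is suspect. This
#' filter removes instruments whose BMI-adjusted exposure association is no
#' longer significant (`p >= p_keep`), tagging them `"bmi_nonrobust"`.
#'
#' @param dat harmonized instruments (or any data.frame with a `snp`
#'   column).
#' @param bmi_adjusted association data.frame of BMI-adjusted exposure
#'   effects; must cover every instrument in `dat`.
#' @param p_keep significance threshold for retention (default 0.05).
#' @return `dat` restricted to robust instruments, with the removed SNPs in
#'   `attr(, "excluded")` (data.frame of `snp`, `adj_pval`, `reason`).
#' @export
exclude_bmi_nonrobust <- function(dat, bmi_adjusted, p_keep = 0.05) {
  bmi_adjusted <- validate_sumstats(bmi_adjusted)
  idx <- match(dat$snp, bmi_adjusted$snp)
  if (any(is.na(idx))) {
    stop("no BMI-adjusted record for: ",
         paste(dat$snp[is.na(idx)], collapse = ", "))
  }
  adj_p <- bmi_adjusted$pval[idx]
  drop <- adj_p >= p_keep
  out <- dat[!drop, , drop = FALSE]
  attr(out, "excluded") <- data.frame(
    snp = as.character(dat$snp[drop]), adj_pval = adj_p[drop],
    reason = rep("bmi_nonrobust", sum(drop)), stringsAsFactors = FALSE)
  out
}

#' Run the full two-sample MR pipeline
#'
#' End-to-end orchestration: harmonize exposure and outcome summary
#' statistics, apply instrument quality control (significance and
#' F-statistic thresholds, optional BMI-robustness filter, optional manual
#' exclusions), run the configured estimators, and compute the diagnostics
#' (Cochran's Q against IVW and Egger, Egger intercept, MR-PRESSO when
#' enough instruments remain, leave-one-out, plot data). With
#' `direction = "reverse"` the roles of the two inputs are swapped.
#'
#' @param exposure,outcome association data.frames (see [read_sumstats()]),
#'   or a fixture list from [load_fixture()] passed as `exposure` with
#'   `outcome` missing.
#' @param direction `"forward"` or `"reverse"` (swap exposure and outcome).
#' @param policy,proxy_directions palindromic-SNP handling, see
#'   [harmonize()].
#' @param p_primary,p_subgroup,f_min,subgroup instrument selection, see
#'   [select_instruments()].
#' @param bmi_adjusted optional BMI-adjusted exposure associations for
#'   [exclude_bmi_nonrobust()].
#' @param exclude_snps optional character vector of SNPs to drop (reason
#'   `"manual"`).
#' @param methods estimators to run, see [mr_all()].
#' @param boot_reps,presso_n_sim stochastic-component sizes.
#' @param seed seed for all stochastic components (required if any run).
#' @return object of class `mr_report`: list with `config`, `instruments`
#'   (selected set), `exclusions` (data.frame with reasons), `single_snp`,
#'   `estimates` (list of `mr_result`), `estimate_table`, `heterogeneity`,
#'   `egger_intercept`, `presso`, `loo`, `plots`.
#' @export
mr_pipeline <- function(exposure, outcome = NULL,
                        direction = c("forward", "reverse"),
                        policy = "eaf-resolve", proxy_directions = NULL,
                        p_primary = 5e-8, p_subgroup = 0.05, f_min = 10,
                        subgroup = FALSE, bmi_adjusted = NULL,
                        exclude_snps = NULL, methods = "all",
                        boot_reps = 1000, presso_n_sim = 1000,
                        seed = NULL) {
  direction <- match.arg(direction)
  if (is.null(outcome) && is.list(exposure) &&
      all(c("exposure", "outcome") %in% names(exposure))) {
    outcome <- exposure$outcome
    exposure <- exposure$exposure
  }
  if (direction == "reverse") {
    tmp <- exposure
    exposure <- outcome
    outcome <- tmp
  }
  if (nrow(exposure) == 0) stop("zero instruments: exposure set is empty")

  dat <- harmonize(exposure, outcome, policy = policy,
                   proxy_directions = proxy_directions)
  sel <- select_instruments(dat, p_primary = p_primary,
                            p_subgroup = p_subgroup, f_min = f_min,
                            subgroup = subgroup)
  exclusions <- data.frame(
    snp = as.character(sel$snp[!sel$selected]),
    reason = sel$exclusion_reason[!sel$selected],
    stringsAsFactors = FALSE)
  dat <- sel[sel$selected, , drop = FALSE]

  if (!is.null(bmi_adjusted)) {
    dat <- exclude_bmi_nonrobust(dat, bmi_adjusted)
    exclusions <- rbind(exclusions,
                        attr(dat, "excluded")[, c("snp", "reason")])
  }
  if (!is.null(exclude_snps)) {
    manual <- dat$snp %in% exclude_snps
    if (any(manual)) {
      exclusions <- rbind(exclusions, data.frame(
        snp = as.character(dat$snp[manual]),
        reason = rep("manual", sum(manual)), stringsAsFactors = FALSE))
      dat <- dat[!manual, , drop = FALSE]
    }
  }
  if (nrow(dat) == 0) {
    stop("zero instruments after QC; exclusions: ",
         paste(exclusions$snp, "(", exclusions$reason, ")", collapse = ", "))
  }

  estimates <- mr_all(dat, methods = methods, boot_reps = boot_reps,
                      seed = seed)
  single <- if (all(dat$bx != 0)) mr_single_snp(dat) else NULL

  het <- list()
  if (nrow(dat) >= 2) het$ivw <- cochran_q(dat, "ivw")
  if (nrow(dat) >= 3 && all(dat$bx > 0)) het$egger <- cochran_q(dat, "egger")
  egger_int <- if (nrow(dat) >= 3 && all(dat$bx > 0)) {
    egger_intercept_test(dat)
  } else NULL
  presso <- if (nrow(dat) >= 4) {
    if (is.null(seed)) stop("seed required for MR-PRESSO")
    mr_presso(dat, n_sim = presso_n_sim, seed = seed + 100L)
  } else NULL
  loo <- if (nrow(dat) >= 3) leave_one_out(dat) else NULL
  plots <- if (length(estimates) > 0) {
    assemble_plot_data(dat, estimates, loo)
  } else NULL

  structure(
    list(config = list(direction = direction, policy = policy,
                       p_primary = p_primary, p_subgroup = p_subgroup,
                       f_min = f_min, subgroup = subgroup,
                       exclude_snps = exclude_snps, methods = methods,
                       boot_reps = boot_reps, presso_n_sim = presso_n_sim,
                       seed = seed),
         instruments = dat, exclusions = exclusions, single_snp = single,
         estimates = estimates, estimate_table = mr_result_table(estimates),
         heterogeneity = het, egger_intercept = egger_int, presso = presso,
         loo = loo, plots = plots),
    class = "mr_report"
  )
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR report (", x$config$direction, " direction, ",
      nrow(x$instruments), " instruments)\n", sep = "")
  if (nrow(x$exclusions) > 0) {
    cat("excluded:", paste0(x$exclusions$snp, " [", x$exclusions$reason,
                            "]", collapse = ", "), "\n")
  }
  tab <- x$estimate_table
  tab$b <- round(tab$b, 3)
  tab$se <- round(tab$se, 3)
  tab$pval <- signif(tab$pval, 3)
  tab$ci_low <- round(tab$ci_low, 3)
  tab$ci_high <- round(tab$ci_high, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept = %.3f (se %.3f, p %.3f)\n",
                x$egger_intercept$intercept, x$egger_intercept$se,
                x$egger_intercept$pval))
  }
  if (!is.null(x$heterogeneity$ivw)) {
    h <- x$heterogeneity$ivw
    cat(sprintf("Cochran's Q (IVW) = %.3f, df = %d, p = %.3f\n",
                h$Q, h$df, h$pval))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("MR-PRESSO global p = %.4g; outliers: %s\n",
                x$presso$global_p,
                if (length(x$presso$outliers)) {
                  paste(x$presso$outliers, collapse = ", ")
                } else "none"))
  }
  invisible(x)
}

#' Serialize an MR report to TSV and JSON files
#'
#' Writes `estimates.tsv`, `instruments.tsv`, `single_snp.tsv`, the plot
#' tables (`funnel.tsv`, `scatter.tsv`, `forest.tsv`, `loo.tsv`) and a
#' machine-readable `report.json` (full precision, provenance included)
#' into `dir`.
#'
#' @param report `mr_report` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mr_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  wt(report$estimate_table, "estimates.tsv")
  wt(as.data.frame(report$instruments), "instruments.tsv")
  wt(report$single_snp, "single_snp.tsv")
  if (!is.null(report$plots)) {
    wt(report$plots$funnel, "funnel.tsv")
    wt(report$plots$scatter_points, "scatter.tsv")
    wt(report$plots$forest, "forest.tsv")
    wt(report$plots$loo, "loo.tsv")
  }
  json <- list(
    config = report$config,
    exclusions = report$exclusions,
    estimates = report$estimate_table,
    heterogeneity = lapply(report$heterogeneity, function(h) {
      h[c("reference", "Q", "df", "pval")]
    }),
    egger_intercept = report$egger_intercept,
    presso = if (!is.null(report$presso)) {
      list(global_rss = report$presso$global_rss,
           global_p = report$presso$global_p,
           outliers = report$presso$outliers,
           distortion_p = report$presso$distortion_p,
           n_sim = report$presso$n_sim, seed = report$presso$seed)
    }
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
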