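#' Load a bundled exposure/outcome summary-statistic fixture
#'
#' The package ships per-SNP association tables transcribed from published
#' instrument tables for circulating leptin (exposure) and anorexia nervosa
#' (outcome, effects on the log-odds scale):
#'
#' * `"gwas_combined"`: 5 genome-wide significant leptin GWAS SNPs
#'   (*LEP*, *SLC32A1*, *GCKR*, *FTO*, *CCNL1*; sexes combined) paired with
#'   their anorexia nervosa associations.
#' * `"gwas_combined_bmi_adj"`: the same 5 SNPs with BMI-adjusted leptin
#'   effect sizes as the exposure.
#' * `"ewas_eur"`: 9 leptin exome-array (EWAS) SNPs in Europeans paired with
#'   their anorexia nervosa associations.
#' * `"ewas_eur_bmi_adj"`: the same 9 SNPs with BMI-adjusted leptin effects.
#'
#' Exposure and outcome effects are reported on a shared effect allele, so
#' `harmonize(..., policy = "keep")` preserves the printed orientation.
#'
#' @param name fixture name, see Details.
#' @return list with elements `exposure` and `outcome`, each a validated
#'   association data.frame.
#' @export
#' @examples
#' fx <- load_fixture("gwas_combined")
#' nrow(fx$exposure)  # 5
load_fixture <- function(name) {
  files <- list(
    gwas_combined = c("leptin_gwas.tsv", "an_for_gwas_snps.tsv"),
    gwas_combined_bmi_adj = c("leptin_gwas_bmi_adj.tsv", "an_for_gwas_snps.tsv"),
    ewas_eur = c("leptin_ewas_eur.tsv", "an_for_ewas_snps.tsv"),
    ewas_eur_bmi_adj = c("leptin_ewas_eur_bmi_adj.tsv", "an_for_ewas_snps.tsv")
  )
  if (!name %in% names(files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(files), collapse = ", "))
  }
  paths <- vapply(files[[name]], function(f) {
    system.file("extdata", f, package = "leptinmr", mustWork = TRUE)
  }, character(1))
  exposure_trait <- if (grepl("^gwas", name)) "leptin_gwas" else "leptin_ewas"
  list(
    exposure = read_sumstats(paths[1], trait_id = exposure_trait),
    outcome = read_sumstats(paths[2], trait_id = "an")
  )
}

#' Proxy-established strand directions for bundled palindromic instruments
#'
#' The leptin GWAS instrument near *LEP* (rs10487505, a C/G variant with
#' allele frequency 0.50) cannot be strand-resolved from allele letters or
#' frequencies. Its orientation was established externally through two
#' non-palindromic variants in high LD (r-squared 0.98), whose leptin and
#' anorexia nervosa effect directions agree with the printed orientation.
#' The A/T *FTO* instrument rs8043757 is likewise confirmed in its printed
#' orientation. Supplying this table to [harmonize()] reproduces the keep
#' decisions under the default `"eaf-resolve"` policy.
#'
#' @return data.frame with columns `snp` and `aligned`.
#' @export
fixture_proxy_directions <- function() {
  data.frame(
    snp = c("rs10487505", "rs8043757"),
    aligned = c(TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
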