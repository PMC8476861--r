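# Shared helpers: quick instrument-set constructors used across test files.

# Harmonized instruments straight from numeric vectors.
make_instruments <- function(bx, by, sy, sx = rep(0.005, length(bx)),
                             snp = sprintf("snp%02d", seq_along(bx))) {
  structure(
    data.frame(snp = snp, ea = "A", oa = "G", bx = bx, sx = sx,
               px = 1e-10, by = by, sy = sy, py = 0.5,
               eaf_x = 0.3, eaf_y = 0.3, palindromic = FALSE,
               flipped = FALSE, stringsAsFactors = FALSE),
    class = c("mr_instruments", "data.frame"))
}

# The 4-SNP leptin GWAS instrument set (FTO variant excluded), harmonized
# with the printed allele orientation.
gwas4 <- function() {
  fx <- load_fixture("gwas_combined")
  dat <- harmonize(fx$exposure, fx$outcome, policy = "keep")
  dat[dat$snp != "rs8043757", ]
}

gwas5 <- function() {
  fx <- load_fixture("gwas_combined")
  harmonize(fx$exposure, fx$outcome, policy = "keep")
}

# EWAS European set after the F >= 10 strength filter (7 instruments).
ewas7 <- function() {
  fx <- load_fixture("ewas_eur")
  dat <- harmonize(fx$exposure, fx$outcome, policy = "keep")
  sel <- select_instruments(dat, subgroup = TRUE)
  sel[sel$selected, ]
}

# Minimal association data.frame for harmonization tests.
assoc <- function(snp, ea, oa, beta, se = 0.01, eaf = NA, pval = 1e-9) {
  data.frame(snp = snp, chr = "1", pos = NA, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = NA, trait = "t",
             stringsAsFactors = FALSE)
}
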