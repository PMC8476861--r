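test_that("reading summary statistics validates and rejects bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")

  # empty file with header -> empty table
  writeLines("snp\tchr\tpos\tea\toa\teaf\tbeta\tse\tpval\tn", path)
  expect_equal(nrow(read_sumstats(path)), 0)

  # a zero standard error violates the se > 0 invariant, with the row indexed
  writeLines(c("snp\tchr\tpos\tea\toa\teaf\tbeta\tse\tpval\tn",
               "rs1\t1\t100\tA\tG\t0.2\t0.05\t0.01\t1e-9\tNA",
               "rs2\t1\t200\tC\tT\t0.4\t0.03\t0\t1e-9\tNA"), path)
  expect_error(read_sumstats(path), "row 2.*se must be > 0")

  # duplicated snp within a trait is an error, not a silent dedup
  writeLines(c("snp\tchr\tpos\tea\toa\teaf\tbeta\tse\tpval\tn",
               "rs1\t1\t100\tA\tG\t0.2\t0.05\t0.01\t1e-9\tNA",
               "rs1\t1\t100\tA\tG\t0.2\t0.05\t0.01\t1e-9\tNA"), path)
  expect_error(read_sumstats(path), "duplicate snp id")

  # a missing mandatory column is reported by name
  writeLines(c("snp\tchr\tea\toa\tse\tpval", "rs1\t1\tA\tG\t0.01\t1e-9"),
             path)
  expect_error(read_sumstats(path), "missing mandatory column.*beta")

  # column_map renames foreign headers
  writeLines(c("rsid\tEA\tOA\tEffect\tStdErr\tP",
               "rs1\tA\tG\t0.05\t0.01\t1e-9"), path)
  x <- read_sumstats(path, column_map = c(snp = "rsid", ea = "EA",
                                          oa = "OA", beta = "Effect",
                                          se = "StdErr", pval = "P"),
                     trait_id = "foreign")
  expect_equal(x$snp, "rs1")
  expect_equal(x$beta, 0.05)
  expect_equal(x$trait, "foreign")
})

test_that("write/read round trip reproduces numeric fields bit-identically", {
  fx <- load_fixture("gwas_combined")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(fx$exposure, path)
  back <- read_sumstats(path, trait_id = "leptin_gwas")
  for (col in c("beta", "se", "pval", "eaf", "pos")) {
    expect_identical(back[[col]], fx$exposure[[col]], label = col)
  }
  # and for generated (full double precision) data
  sim <- simulate_summary_stats(J = 10, theta = 0.3, seed = 11)
  write_sumstats(sim$exposure, path)
  back <- read_sumstats(path)
  expect_identical(back$beta, sim$exposure$beta)
  expect_identical(back$se, sim$exposure$se)
})

test_that("odds ratios convert to log-odds effects", {
  expect_identical(or_to_beta(1), 0)
  # natural logs computed independently (frozen from log tables)
  expect_equal(or_to_beta(1.08), 0.076961, tolerance = 1e-5)
  expect_equal(or_to_beta(0.5), -0.693147, tolerance = 1e-5)
  expect_error(or_to_beta(0), "positive")
  expect_error(or_to_beta(-2), "positive")
})

test_that("palindromic classification recognises strand-ambiguous pairs", {
  expect_true(is_palindromic("C", "G"))   # the LEP lead variant's alleles
  expect_true(is_palindromic("T", "A"))
  expect_false(is_palindromic("A", "C"))
  expect_false(is_palindromic("G", "A"))
  expect_equal(is_palindromic(c("A", "C"), c("T", "A")), c(TRUE, FALSE))
  expect_error(is_palindromic("A", "N"), "A/C/G/T")
})

test_that("harmonize aligns, swaps and strand-complements outcome alleles", {
  ex <- assoc("rs1", "A", "G", beta = 0.02)

  # same orientation: untouched
  h <- harmonize(ex, assoc("rs1", "A", "G", beta = -0.05),
                 exposure_positive = FALSE)
  expect_equal(h$by, -0.05)
  expect_false(h$flipped)

  # outcome reports the other allele: effect sign flips
  h <- harmonize(ex, assoc("rs1", "G", "A", beta = -0.05, eaf = 0.7),
                 exposure_positive = FALSE)
  expect_equal(h$by, 0.05)
  expect_true(h$flipped)
  expect_equal(h$eaf_y, 0.3)

  # outcome on the opposite strand: complement resolves it
  h <- harmonize(ex, assoc("rs1", "T", "C", beta = -0.05),
                 exposure_positive = FALSE)
  expect_equal(h$by, -0.05)
  h <- harmonize(ex, assoc("rs1", "C", "T", beta = -0.05),
                 exposure_positive = FALSE)
  expect_equal(h$by, 0.05)

  # incompatible alleles are an error
  expect_error(
    harmonize(ex, assoc("rs1", "A", "C", beta = -0.05)),
    "allele mismatch")
})

test_that("palindromic policies resolve, keep or drop ambiguous SNPs", {
  ex <- assoc("rs1", "C", "G", beta = 0.02, eaf = 0.2)

  # strict drops all palindromic SNPs
  expect_warning(
    h <- harmonize(ex, assoc("rs1", "C", "G", beta = -0.05, eaf = 0.2),
                   policy = "strict"),
    "palindromic")
  expect_equal(nrow(h), 0)

  # eaf-resolve: frequencies agree -> printed orientation kept
  h <- harmonize(ex, assoc("rs1", "C", "G", beta = -0.05, eaf = 0.25))
  expect_equal(h$by, -0.05)

  # frequencies on opposite sides of 0.5 -> strand flip, sign flips
  h <- harmonize(ex, assoc("rs1", "C", "G", beta = -0.05, eaf = 0.75))
  expect_equal(h$by, 0.05)

  # uninformative frequency falls through to the proxy-direction table
  h <- harmonize(ex, assoc("rs1", "C", "G", beta = -0.05, eaf = 0.5),
                 proxy_directions = data.frame(snp = "rs1", aligned = TRUE))
  expect_equal(h$by, -0.05)
  h <- harmonize(ex, assoc("rs1", "C", "G", beta = -0.05, eaf = 0.5),
                 proxy_directions = data.frame(snp = "rs1", aligned = FALSE))
  expect_equal(h$by, 0.05)

  # without proxy information the SNP is dropped with a warning
  expect_warning(
    h <- harmonize(ex, assoc("rs1", "C", "G", beta = -0.05, eaf = 0.5)),
    "unresolvable palindromic")
  expect_equal(nrow(h), 0)
})

test_that("exposure-positive orientation flips both effects and alleles", {
  # the EWAS LEP variant prints a negative leptin effect
  fx <- load_fixture("ewas_eur")
  h <- harmonize(fx$exposure, fx$outcome, policy = "keep")
  lep <- h[h$snp == "rs791600", ]
  expect_equal(lep$bx, 0.043)
  expect_equal(lep$by, -0.039)
  expect_equal(lep$ea, "G")  # alleles swapped relative to the printed A/G
  expect_equal(lep$eaf_x, 1 - 0.411)
  expect_true(all(h$bx >= 0))
})

test_that("harmonization is involution-safe", {
  fx <- load_fixture("gwas_combined")
  h1 <- harmonize(fx$exposure, fx$outcome, policy = "keep")
  # reconstruct association tables from the harmonized set and re-harmonize
  ex2 <- data.frame(snp = h1$snp, ea = h1$ea, oa = h1$oa, eaf = h1$eaf_x,
                    beta = h1$bx, se = h1$sx, pval = h1$px,
                    stringsAsFactors = FALSE)
  ou2 <- data.frame(snp = h1$snp, ea = h1$ea, oa = h1$oa, eaf = h1$eaf_y,
                    beta = h1$by, se = h1$sy, pval = h1$py,
                    stringsAsFactors = FALSE)
  h2 <- harmonize(ex2, ou2, policy = "keep")
  expect_equal(h2$bx, h1$bx)
  expect_equal(h2$by, h1$by)
  expect_equal(h2$ea, h1$ea)
})

test_that("bundled fixtures load the transcribed instrument tables", {
  fx <- load_fixture("gwas_combined")
  expect_equal(nrow(fx$exposure), 5)
  expect_setequal(fx$exposure$snp,
                  c("rs10487505", "rs6071166", "rs780093", "rs8043757",
                    "rs900400"))
  expect_equal(fx$exposure$beta[fx$exposure$snp == "rs10487505"], 0.023)
  expect_equal(fx$outcome$beta[fx$outcome$snp == "rs10487505"], -0.032)

  fx <- load_fixture("ewas_eur")
  expect_equal(nrow(fx$exposure), 9)
  expect_equal(fx$exposure$beta[fx$exposure$snp == "rs791600"], -0.043)

  fx <- load_fixture("gwas_combined_bmi_adj")
  expect_equal(fx$exposure$pval[fx$exposure$snp == "rs8043757"], 0.84)

  expect_error(load_fixture("nonexistent"), "unknown fixture")
})
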