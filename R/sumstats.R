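#' @importFrom stats approx coef dnorm lm mad pchisq pnorm pt qnorm
#'   residuals rnorm runif sd uniroot
#' @importFrom utils read.delim write.table
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Standard column names of the summary-statistic table dialect
#'
#' Per-SNP association tables use columns `snp`, `chr`, `pos`, `ea`
#' (effect allele), `oa` (other allele), `eaf` (effect-allele frequency),
#' `beta`, `se`, `pval`, `n` and `trait`. Missing optional values are `NA`.
#' @keywords internal
SUMSTATS_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf",
                   "beta", "se", "pval", "n", "trait")

#' Validate a summary-association table
#'
#' Checks the per-row invariants of a SNP-trait association table: positive
#' standard errors, p-values in (0, 1], distinct single-base alleles, allele
#' frequencies in \[0, 1\] when present, and unique SNP ids within a trait.
#'
#' @param x data.frame with at least `snp`, `ea`, `oa`, `beta`, `se`, `pval`.
#' @return `x` invisibly (with missing optional columns added as `NA`),
#'   or an error whose message indexes the offending rows.
#' @export
validate_sumstats <- function(x) {
  stopifnot(is.data.frame(x))
  mandatory <- c("snp", "ea", "oa", "beta", "se", "pval")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(SUMSTATS_COLS, names(x))) {
    x[[col]] <- rep(NA, nrow(x))
  }
  x <- x[, SUMSTATS_COLS]
  x$snp <- as.character(x$snp)
  x$chr <- as.character(x$chr)
  x$ea <- toupper(as.character(x$ea))
  x$oa <- toupper(as.character(x$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  if (nrow(x) == 0) return(invisible(x))

  problems <- character(0)
  bad <- function(idx, what) {
    if (any(idx, na.rm = TRUE)) {
      problems <<- c(problems, paste0(
        "row ", paste(which(idx), collapse = ","), ": ", what))
    }
  }
  bad(is.na(x$beta), "beta is missing or unparsable")
  bad(is.na(x$se), "se is missing or unparsable")
  bad(!is.na(x$se) & x$se <= 0, "se must be > 0")
  bad(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "pval must be in (0, 1]")
  bad(!(x$ea %in% VALID_ALLELES), "effect allele must be one of A/C/G/T")
  bad(!(x$oa %in% VALID_ALLELES), "other allele must be one of A/C/G/T")
  bad(x$ea == x$oa, "effect and other allele must differ")
  bad(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf must be in [0, 1]")

  dup <- duplicated(paste(x$trait, x$snp))
  if (any(dup)) {
    problems <- c(problems, paste0(
      "duplicate snp id within trait: ",
      paste(unique(x$snp[dup]), collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("invalid summary statistics:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(x)
}

#' Read per-SNP summary statistics from a TSV file
#'
#' Reads a tab-separated association table in the standard dialect
#' (columns `snp`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`,
#' `n`; `NA` for missing values). Foreign headers are accommodated via
#' `column_map`. Every row is validated against the type invariants;
#' violations are rejected with row-indexed messages rather than dropped.
#'
#' @param path path to a TSV file with a header row.
#' @param column_map optional named character vector mapping standard names
#'   to the file's column names, e.g. `c(snp = "rsid", beta = "Effect")`.
#' @param trait_id optional trait label stored in the `trait` column.
#' @return validated data.frame of associations.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                    colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(raw)) {
        stop("column_map refers to absent column: ", src)
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  keep <- intersect(SUMSTATS_COLS, names(raw))
  out <- raw[, keep, drop = FALSE]
  if (!is.null(trait_id)) out$trait <- trait_id
  validate_sumstats(out)
}

#' Write summary statistics in the standard TSV dialect
#'
#' Numeric fields are written with full precision (up to 17 significant
#' digits) so that a write/read round trip reproduces them bit-identically.
#'
#' @param x validated association data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  x <- validate_sumstats(x)
  out <- x[, setdiff(SUMSTATS_COLS, "trait")]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         format(out[[col]], digits = 17, trim = TRUE,
                                scientific = FALSE))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Convert an odds ratio to a log-odds effect size
#'
#' Binary-trait (e.g. anorexia nervosa case/control) effects are consumed on
#' the log-odds scale throughout; published odds ratios are converted with
#' the natural logarithm.
#'
#' @param odds_ratio positive odds ratio(s).
#' @return `log(odds_ratio)`.
#' @export
or_to_beta <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("odds ratio must be positive and finite")
  }
  log(odds_ratio)
}

#' Is an allele pair palindromic (strand-ambiguous)?
#'
#' A/T and C/G pairs read the same on both strands, so the effect allele
#' cannot be resolved from allele letters alone.
#'
#' @param effect_allele,other_allele single-base alleles (A/C/G/T).
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  if (any(!(ea %in% VALID_ALLELES)) || any(!(oa %in% VALID_ALLELES))) {
    stop("alleles must be single bases A/C/G/T")
  }
  unname(.complement[ea] == oa)
}

#' Harmonize exposure and outcome associations onto a common orientation
#'
#' Matches SNPs present in both studies, expresses the outcome effect for the
#' exposure's effect allele (sign-flipping when the outcome reports the other
#' allele, complementing first when the studies used opposite strands), and
#' resolves strand-ambiguous (palindromic) variants according to `policy`:
#'
#' * `"eaf-resolve"` (default): use allele frequencies when informative
#'   (`|eaf - 0.5| > eaf_tol` in both studies); otherwise consult
#'   `proxy_directions`; otherwise drop the SNP with a warning.
#' * `"strict"`: drop all palindromic SNPs with a warning.
#' * `"keep"`: trust the printed allele orientation as-is (appropriate for
#'   curated tables where exposure and outcome effects are already reported
#'   on a shared effect allele).
#'
#' Under `exposure_positive = TRUE` every instrument is re-oriented so the
#' exposure effect is non-negative (both betas sign-flipped, alleles swapped,
#' frequencies complemented); all downstream estimators are invariant to this
#' joint flip, and MR-Egger requires it.
#'
#' @param exposure,outcome validated association data.frames.
#' @param policy palindromic-SNP policy, see Details.
#' @param eaf_tol minimum distance of the allele frequency from 0.5 for it to
#'   be considered strand-informative (default 0.08).
#' @param proxy_directions optional data.frame with columns `snp` and
#'   `aligned` (logical): externally established (e.g. via LD proxies)
#'   statement that the outcome record's printed orientation is correct
#'   (`TRUE`) or needs flipping (`FALSE`).
#' @param exposure_positive re-orient instruments so `bx >= 0` (default TRUE).
#' @return data.frame of class `mr_instruments` with columns `snp`, `ea`,
#'   `oa`, `bx`, `sx`, `px`, `by`, `sy`, `py`, `eaf_x`, `eaf_y`,
#'   `palindromic`, `flipped`.
#' @export
harmonize <- function(exposure, outcome,
                      policy = c("eaf-resolve", "strict", "keep"),
                      eaf_tol = 0.08, proxy_directions = NULL,
                      exposure_positive = TRUE) {
  policy <- match.arg(policy)
  exposure <- validate_sumstats(exposure)
  outcome <- validate_sumstats(outcome)
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) stop("no shared SNPs between exposure and outcome")
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]

  n <- length(shared)
  by <- ou$beta
  eaf_y <- ou$eaf
  flipped <- logical(n)
  drop <- logical(n)
  palin <- is_palindromic(ex$ea, ex$oa)

  for (i in seq_len(n)) {
    a <- c(ex$ea[i], ex$oa[i])
    b <- c(ou$ea[i], ou$oa[i])
    b_c <- unname(.complement[b])
    if (identical(b, a)) {
      aligned <- TRUE
    } else if (identical(b, rev(a))) {
      aligned <- FALSE
    } else if (identical(b_c, a)) {
      aligned <- TRUE
    } else if (identical(b_c, rev(a))) {
      aligned <- FALSE
    } else {
      stop("allele mismatch for ", shared[i], ": exposure ",
           paste(a, collapse = "/"), " vs outcome ", paste(b, collapse = "/"))
    }
    if (!aligned) {
      by[i] <- -by[i]
      eaf_y[i] <- 1 - eaf_y[i]
      flipped[i] <- TRUE
    }

    if (palin[i] && policy != "keep") {
      if (policy == "strict") {
        drop[i] <- TRUE
        next
      }
      # eaf-resolve: frequencies of the exposure effect allele in both studies
      fx <- ex$eaf[i]
      fy <- eaf_y[i]
      if (!is.na(fx) && !is.na(fy) &&
          abs(fx - 0.5) > eaf_tol && abs(fy - 0.5) > eaf_tol) {
        if ((fx > 0.5) != (fy > 0.5)) {
          # outcome allele labels refer to the opposite strand sense
          by[i] <- -by[i]
          eaf_y[i] <- 1 - eaf_y[i]
          flipped[i] <- !flipped[i]
        }
      } else if (!is.null(proxy_directions) &&
                 shared[i] %in% proxy_directions$snp) {
        j <- match(shared[i], proxy_directions$snp)
        if (!isTRUE(proxy_directions$aligned[j])) {
          by[i] <- -by[i]
          eaf_y[i] <- 1 - eaf_y[i]
          flipped[i] <- !flipped[i]
        }
      } else {
        drop[i] <- TRUE
      }
    }
  }

  if (any(drop)) {
    warning("dropping unresolvable palindromic SNP(s): ",
            paste(shared[drop], collapse = ", "))
  }

  out <- data.frame(
    snp = shared, ea = ex$ea, oa = ex$oa,
    bx = ex$beta, sx = ex$se, px = ex$pval,
    by = by, sy = ou$se, py = ou$pval,
    eaf_x = ex$eaf, eaf_y = eaf_y,
    palindromic = palin, flipped = flipped,
    stringsAsFactors = FALSE
  )
  out <- out[!drop, , drop = FALSE]

  if (exposure_positive) {
    neg <- !is.na(out$bx) & out$bx < 0
    if (any(neg)) {
      tmp <- out$ea[neg]
      out$ea[neg] <- out$oa[neg]
      out$oa[neg] <- tmp
      out$bx[neg] <- -out$bx[neg]
      out$by[neg] <- -out$by[neg]
      out$eaf_x[neg] <- 1 - out$eaf_x[neg]
      out$eaf_y[neg] <- 1 - out$eaf_y[neg]
    }
  }
  rownames(out) <- NULL
  class(out) <- c("mr_instruments", "data.frame")
  out
}
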