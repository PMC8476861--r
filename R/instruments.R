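#' Instrument strength F-statistic
#'
#' The approximate first-stage F-statistic of a single genetic instrument,
#' `(beta/se)^2`. Values below 10 conventionally flag weak instruments.
#'
#' @param beta,se per-allele effect and positive standard error.
#' @return F-statistic(s), invariant to the sign of `beta`.
#' @export
#' @examples
#' f_statistic(0.032, 0.005)  # 40.96
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Select genetic instruments by significance and strength
#'
#' Applies the instrument quality-control rules: the exposure association
#' must be stronger than F >= `f_min` (weak-instrument filter) and its
#' p-value must fall below the applicable significance threshold
#' (genome-wide `p_primary` by default; the relaxed `p_subgroup` threshold
#' is opt-in for instruments carried over from a larger discovery sample
#' into a subgroup where they need not reach genome-wide significance).
#'
#' @param x association data.frame (exposure study) or `mr_instruments`
#'   (columns `bx`, `sx`, `px` are then used).
#' @param p_primary genome-wide significance threshold (default 5e-8).
#' @param p_subgroup relaxed threshold (default 0.05), used when
#'   `subgroup = TRUE`.
#' @param f_min minimum instrument strength; SNPs with F < `f_min` are
#'   excluded (boundary kept: F equal to `f_min` is retained).
#' @param subgroup apply the relaxed significance threshold.
#' @return the input with added columns `f_stat`, `selected` and
#'   `exclusion_reason` (`"weak_instrument"`, `"nonsignificant"` or `""`);
#'   row order is preserved and the operation is idempotent.
#' @export
select_instruments <- function(x, p_primary = 5e-8, p_subgroup = 0.05,
                               f_min = 10, subgroup = FALSE) {
  if (nrow(x) == 0) {
    x$f_stat <- numeric(0)
    x$selected <- logical(0)
    x$exclusion_reason <- character(0)
    return(x)
  }
  if (all(c("bx", "sx", "px") %in% names(x))) {
    beta <- x$bx; se <- x$sx; pval <- x$px
  } else {
    beta <- x$beta; se <- x$se; pval <- x$pval
  }
  f <- f_statistic(beta, se)
  p_thresh <- if (subgroup) p_subgroup else p_primary
  reason <- ifelse(f < f_min, "weak_instrument",
                   ifelse(pval >= p_thresh, "nonsignificant", ""))
  x$f_stat <- f
  x$selected <- reason == ""
  x$exclusion_reason <- reason
  x
}

#' Choose an LD proxy for an instrument absent from the outcome study
#'
#' Ranks candidate proxies by: (1) highest LD r-squared with the lead SNP,
#' (2) smallest distance to the lead SNP, (3) preferring non-palindromic
#' (strand-unambiguous) alleles, with a final lexicographic SNP-id
#' tie-break for determinism. Candidates below `r2_min` are ineligible.
#'
#' @param candidates data.frame with columns `snp`, `r2`, `distance`, `ea`,
#'   `oa` (read from a TSV; no live LD queries are performed).
#' @param r2_min minimum LD with the lead SNP (default 0.80).
#' @return the selected candidate row (one-row data.frame), or `NULL` when
#'   no candidate passes.
#' @export
select_proxy <- function(candidates, r2_min = 0.80) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  stopifnot(all(c("snp", "r2", "distance", "ea", "oa") %in% names(candidates)))
  if (any(candidates$r2 < 0 | candidates$r2 > 1)) {
    stop("r2 must be in [0, 1]")
  }
  ok <- candidates[candidates$r2 >= r2_min, , drop = FALSE]
  if (nrow(ok) == 0) return(NULL)
  palin <- is_palindromic(ok$ea, ok$oa)
  o <- order(-ok$r2, ok$distance, palin, ok$snp)
  ok[o[1], , drop = FALSE]
}
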