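#' Methylation percentage from read counts
#'
#' The methylation level of a CpG (or pooled region) is the ratio of
#' methylated read counts over the sum of methylated and unmethylated
#' counts, times 100.
#'
#' @param meth_count,unmeth_count Non-negative integer vectors.
#' @return Numeric vector of percentages in \[0, 100\].
#' @export
methylation_percent <- function(meth_count, unmeth_count) {
  cov <- meth_count + unmeth_count
  if (any(cov == 0)) {
    stopf("methylation_percent undefined at zero coverage (%d site(s)); filter first",
          sum(cov == 0))
  }
  100 * meth_count / cov
}

#' Filter CpG sites by read coverage
#'
#' Retains sites whose total coverage (methylated + unmethylated reads) is
#' at least `min_coverage`. The default of 10 follows the usual convention
#' for RRBS differential-methylation calling.
#'
#' @param calls Methylation-call data frame (`chrom`, `pos`, `meth`, `unmeth`).
#' @param min_coverage Minimum coverage, inclusive; must be >= 1.
#' @return The filtered table, original order preserved.
#' @export
filter_coverage <- function(calls, min_coverage = 10L) {
  if (min_coverage < 1) stopf("min_coverage must be >= 1")
  keep <- (calls$meth + calls$unmeth) >= min_coverage
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(calls, "sample_id")
  out
}

#' Vectorized two-sided Fisher exact test for 2x2 count tables
#'
#' Classical two-sided definition: the p-value is the sum of hypergeometric
#' point probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (relative tie
#' tolerance 1e-12). Row 1 of table i is `(a[i], b[i])`, row 2 is
#' `(c[i], d[i])`.
#'
#' @param a,b,c,d Non-negative integer vectors of equal length.
#' @return Numeric vector of p-values.
#' @export
fisher_test_counts <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stopf("counts must be non-negative")
  n <- length(a)
  if (n == 0L) return(numeric(0))
  m1 <- a + b          # row-1 margin (white balls)
  m2 <- c + d          # row-2 margin (black balls)
  k <- a + c           # column-1 margin (balls drawn)
  lo <- pmax(0L, k - m2)
  hi <- pmin(k, m1)
  len <- hi - lo + 1L
  idx <- rep.int(seq_len(n), len)
  x <- sequence(len) - 1L + rep.int(lo, len)
  logd <- stats::dhyper(x, m1[idx], m2[idx], k[idx], log = TRUE)
  logd_obs <- stats::dhyper(a, m1, m2, k, log = TRUE)
  keep <- logd <= logd_obs[idx] + log1p(1e-12)
  p <- rowsum(ifelse(keep, exp(logd), 0), idx, reorder = TRUE)[, 1]
  unname(pmin(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: `q_(i) = min over j >= i of
#' (m * p_(j) / j)`, clipped to 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-individual paired differential methylation site test
#'
#' For one individual's coverage-filtered P2 and P10 call tables, tests each
#' CpG present in both samples with a two-sided Fisher exact test on the
#' 2x2 table of methylated/unmethylated read counts, then applies
#' Benjamini-Hochberg adjustment across all CpGs tested for this individual.
#' A site is a DMS iff `q_value < fdr` and `|meth_diff| >= min_diff`.
#'
#' @param p2,p10 Coverage-filtered methylation-call tables for the two ages.
#' @param fdr False discovery rate threshold (default 0.05).
#' @param min_diff Minimum absolute methylation difference in percentage
#'   points (default 0: the FDR criterion alone decides).
#' @param individual_id Identifier recorded in the output rows.
#' @return A list with `tested` (all shared CpGs: `individual_id`, `chrom`,
#'   `pos`, `meth_p2`, `meth_p10`, `meth_diff` = P10 - P2, `p_value`,
#'   `q_value`, `significant`) and `dms` (the significant subset).
#' @export
paired_dms_test <- function(p2, p10, fdr = 0.05, min_diff = 0,
                            individual_id = NA_character_) {
  key2 <- site_key(p2$chrom, p2$pos)
  key10 <- site_key(p10$chrom, p10$pos)
  i2 <- which(key2 %in% key10)
  if (length(i2) == 0L) {
    warning(sprintf("no shared CpGs between P2 and P10 for individual %s",
                    individual_id), call. = FALSE)
    empty <- data.frame(individual_id = character(), chrom = character(),
                        pos = integer(), meth_p2 = numeric(),
                        meth_p10 = numeric(), meth_diff = numeric(),
                        p_value = numeric(), q_value = numeric(),
                        significant = logical(), stringsAsFactors = FALSE)
    return(list(tested = empty, dms = empty))
  }
  i10 <- match(key2[i2], key10)
  meth_p2 <- methylation_percent(p2$meth[i2], p2$unmeth[i2])
  meth_p10 <- methylation_percent(p10$meth[i10], p10$unmeth[i10])
  p <- fisher_test_counts(p2$meth[i2], p2$unmeth[i2],
                          p10$meth[i10], p10$unmeth[i10])
  q <- bh_adjust(p)
  diff <- meth_p10 - meth_p2
  tested <- data.frame(individual_id = individual_id,
                       chrom = p2$chrom[i2], pos = p2$pos[i2],
                       meth_p2 = meth_p2, meth_p10 = meth_p10,
                       meth_diff = diff, p_value = p, q_value = q,
                       significant = q < fdr & abs(diff) >= min_diff,
                       stringsAsFactors = FALSE)
  tested <- tested[order(tested$chrom, tested$pos), , drop = FALSE]
  rownames(tested) <- NULL
  list(tested = tested, dms = tested[tested$significant, , drop = FALSE])
}
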