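#' Assemble the DMR-by-sample methylation matrix
#'
#' Each cell is the pooled region methylation of a region in a sample
#' (see [region_methylation()]). Rows whose missing fraction exceeds
#' `max_missing_frac` are dropped (count reported via message); remaining
#' missing cells are imputed with the row mean.
#'
#' @param regions Region data frame from [merge_sites()] (non-empty,
#'   non-overlapping per chromosome).
#' @param tables Named list of methylation-call tables; names must cover
#'   `manifest$sample_id`.
#' @param manifest Validated manifest with a `sample_id` column.
#' @param max_missing_frac Maximum tolerated fraction of missing samples
#'   per region (default 0.2).
#' @return List with `values` (regions x samples matrix, percent scale),
#'   `col_data` (per-column manifest rows) and `n_dropped`.
#' @export
build_matrix <- function(regions, tables, manifest, max_missing_frac = 0.2) {
  if (nrow(regions) == 0L) stopf("no regions to quantify")
  missing_tabs <- setdiff(manifest$sample_id, names(tables))
  if (length(missing_tabs)) {
    stopf("no call table for sample(s): %s", paste(missing_tabs, collapse = ", "))
  }
  o <- order(regions$chrom, regions$start_pos)
  regions <- regions[o, , drop = FALSE]
  nreg <- nrow(regions)
  samples <- manifest$sample_id
  M <- matrix(NA_real_, nreg, length(samples),
              dimnames = list(regions$region_id, samples))
  by_chrom <- split(seq_len(nreg), regions$chrom)
  for (s in samples) {
    tab <- tables[[s]]
    for (chrom in names(by_chrom)) {
      ri <- by_chrom[[chrom]]
      in_chrom <- tab$chrom == chrom
      if (!any(in_chrom)) next
      pos <- tab$pos[in_chrom]
      fi <- findInterval(pos, regions$start_pos[ri])
      ok <- fi >= 1L & pos <= regions$end_pos[ri][pmax(fi, 1L)]
      if (!any(ok)) next
      reg_of_site <- ri[fi[ok]]
      meth <- rowsum(tab$meth[in_chrom][ok], reg_of_site)
      tot <- rowsum(tab$meth[in_chrom][ok] + tab$unmeth[in_chrom][ok],
                    reg_of_site)
      M[as.integer(rownames(meth)), s] <- 100 * meth[, 1] / tot[, 1]
    }
  }
  miss_frac <- rowMeans(is.na(M))
  drop <- miss_frac > max_missing_frac
  if (all(drop)) {
    stopf("all %d regions exceed max_missing_frac = %g; lower the coverage or missingness thresholds",
          nreg, max_missing_frac)
  }
  if (any(drop)) {
    message(sprintf("build_matrix: dropped %d/%d regions with missing fraction > %g",
                    sum(drop), nreg, max_missing_frac))
  }
  M <- M[!drop, , drop = FALSE]
  na_idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na_idx)) {
    rm_ <- rowMeans(M, na.rm = TRUE)
    M[na_idx] <- rm_[na_idx[, 1]]
  }
  col_data <- manifest[match(samples, manifest$sample_id), , drop = FALSE]
  rownames(col_data) <- NULL
  list(values = M, col_data = col_data, n_dropped = sum(drop))
}

#' Intra-individual delta methylation: log2(P10 / P2)
#'
#' For each region and individual, `log2((P10% + epsilon) / (P2% + epsilon))`.
#' Positive values mean higher methylation at P10. The symmetric pseudocount
#' `epsilon` (percentage points) guards division by zero and log of zero
#' while preserving zero at equality.
#'
#' @param values Regions x samples percent matrix (columns named by
#'   sample ID).
#' @param col_data Per-column metadata with `sample_id`, `individual_id`,
#'   `age`, `group`, `cohort`.
#' @param epsilon Pseudocount in percentage points, > 0 (default 1).
#' @return List with `values` (regions x individuals log2-ratio matrix) and
#'   `col_data` (per-individual `individual_id`, `group`, `cohort`).
#' @export
delta_methylation <- function(values, col_data, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stopf("epsilon must be a single positive number")
  }
  individuals <- unique(col_data$individual_id)
  cols <- colnames(values) %||% col_data$sample_id
  s2 <- match(paste(individuals, "P2", sep = "_"), cols)
  s10 <- match(paste(individuals, "P10", sep = "_"), cols)
  if (anyNA(s2) || anyNA(s10)) {
    stopf("both ages must be present for every individual")
  }
  meta_idx <- match(paste(individuals, "P2", sep = "_"), col_data$sample_id)
  delta <- log2((values[, s10, drop = FALSE] + epsilon) /
                (values[, s2, drop = FALSE] + epsilon))
  colnames(delta) <- individuals
  meta <- data.frame(individual_id = individuals,
                     group = col_data$group[meta_idx],
                     cohort = col_data$cohort[meta_idx],
                     stringsAsFactors = FALSE)
  list(values = delta, col_data = meta)
}

#' Remove a batch effect by per-feature mean alignment
#'
#' For every feature (row), each value is replaced by
#' `value - (its batch mean) + (grand mean of the feature)`, so batch means
#' become equal across batches while differences between samples of the
#' same batch are preserved exactly.
#'
#' @param values Features x samples numeric matrix.
#' @param batches Per-sample batch labels (length = ncol).
#' @return Corrected matrix of the same shape.
#' @export
remove_batch_effect <- function(values, batches) {
  if (length(batches) != ncol(values)) {
    stopf("length(batches) must equal ncol(values)")
  }
  ub <- unique(batches)
  if (length(ub) < 2L) {
    warning("single batch: matrix returned unchanged", call. = FALSE)
    return(values)
  }
  gm <- rowMeans(values)
  out <- values
  for (b in ub) {
    idx <- which(batches == b)
    bm <- rowMeans(values[, idx, drop = FALSE])
    out[, idx] <- values[, idx, drop = FALSE] - bm + gm
  }
  out
}
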