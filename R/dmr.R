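#' Count how many individuals of each group share each DMS
#'
#' A site is "shared" by the individuals in which it was called significant.
#' Counts distinct control and LBN individuals per (chrom, pos).
#'
#' @param dms_by_individual Named list (names = individual IDs) of DMS data
#'   frames, each with columns `chrom` and `pos`.
#' @param manifest Validated sample manifest (supplies each individual's
#'   group).
#' @return Data frame `chrom`, `pos`, `n_control`, `n_lbn`, sorted by
#'   (chrom, pos); empty when no individual has DMSs.
#' @export
sharing_counts <- function(dms_by_individual, manifest) {
  grp <- manifest$group[match(names(dms_by_individual),
                              manifest$individual_id)]
  if (anyNA(grp)) {
    stopf("individual(s) absent from manifest: %s",
          paste(names(dms_by_individual)[is.na(grp)], collapse = ", "))
  }
  pieces <- lapply(seq_along(dms_by_individual), function(i) {
    d <- dms_by_individual[[i]]
    if (nrow(d) == 0L) return(NULL)
    unique(data.frame(chrom = d$chrom, pos = d$pos, group = grp[i],
                      stringsAsFactors = FALSE))
  })
  all <- do.call(rbind, pieces)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      n_control = integer(), n_lbn = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- site_key(all$chrom, all$pos)
  ctl <- rowsum(as.integer(all$group == "control"), key, reorder = FALSE)
  lbn <- rowsum(as.integer(all$group == "LBN"), key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chrom = all$chrom[first], pos = all$pos[first],
                    n_control = ctl[match(key[first], rownames(ctl)), 1],
                    n_lbn = lbn[match(key[first], rownames(lbn)), 1],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sharing histogram: number of sites per sharing count
#'
#' Tabulates, for each total number of individuals sharing a DMS
#' (control + LBN), how many sites have that sharing count.
#'
#' @param counts Output of [sharing_counts()].
#' @return Data frame `n_sharing`, `n_sites`.
#' @export
sharing_histogram <- function(counts) {
  total <- counts$n_control + counts$n_lbn
  if (length(total) == 0L) {
    return(data.frame(n_sharing = integer(), n_sites = integer()))
  }
  tab <- table(total)
  data.frame(n_sharing = as.integer(names(tab)),
             n_sites = as.integer(tab))
}

#' Keep sites shared by enough individuals of one group
#'
#' Default rule (`"either"`): a site is kept iff at least `min_individuals`
#' control individuals OR at least `min_individuals` LBN individuals share
#' it. `rule = "both"` requires the threshold in each group.
#'
#' @param counts Output of [sharing_counts()].
#' @param min_individuals Sharing threshold, >= 1 (default 2).
#' @param rule `"either"` (default) or `"both"`.
#' @return The subset of `counts` passing the filter.
#' @export
filter_shared <- function(counts, min_individuals = 2L,
                          rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (min_individuals < 1) stopf("min_individuals must be >= 1")
  keep <- if (rule == "either") {
    counts$n_control >= min_individuals | counts$n_lbn >= min_individuals
  } else {
    counts$n_control >= min_individuals & counts$n_lbn >= min_individuals
  }
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby sites into regions
#'
#' Single-linkage chaining per chromosome: a region grows while the next
#' site is within `merge_gap` base pairs of the previous one (inclusive at
#' exactly `merge_gap`). Regions never span chromosomes. Region IDs are
#' deterministic (`chrom:start-end`).
#'
#' @param sites Data frame with columns `chrom` and `pos` (duplicates are
#'   collapsed; any order accepted).
#' @param merge_gap Maximum distance in bp between consecutive member sites
#'   (default 100).
#' @return Data frame `region_id`, `chrom`, `start_pos`, `end_pos`,
#'   `n_sites`, plus a list-column `members` of member positions; sorted by
#'   (chrom, start_pos).
#' @export
merge_sites <- function(sites, merge_gap = 100L) {
  if (nrow(sites) == 0L) {
    return(data.frame(region_id = character(), chrom = character(),
                      start_pos = integer(), end_pos = integer(),
                      n_sites = integer(),
                      members = I(list()), stringsAsFactors = FALSE))
  }
  u <- unique(data.frame(chrom = sites$chrom, pos = sites$pos,
                         stringsAsFactors = FALSE))
  u <- u[order(u$chrom, u$pos), , drop = FALSE]
  n <- nrow(u)
  new_region <- c(TRUE, u$chrom[-1] != u$chrom[-n] |
                        u$pos[-1] - u$pos[-n] > merge_gap)
  grp <- cumsum(new_region)
  members <- split(u$pos, grp)
  first <- !duplicated(grp)
  start_pos <- vapply(members, min, integer(1))
  end_pos <- vapply(members, max, integer(1))
  chrom <- u$chrom[first]
  out <- data.frame(region_id = sprintf("%s:%d-%d", chrom, start_pos, end_pos),
                    chrom = chrom, start_pos = start_pos, end_pos = end_pos,
                    n_sites = lengths(members), stringsAsFactors = FALSE)
  out$members <- unname(members)
  rownames(out) <- NULL
  out
}

#' Annotate regions with group sharing support
#'
#' For each region, `support_control` / `support_lbn` is the maximum
#' per-site sharing count over the region's member sites in that group.
#'
#' @param regions Output of [merge_sites()].
#' @param counts Output of [sharing_counts()].
#' @return `regions` with `support_control` and `support_lbn` columns.
#' @export
region_support <- function(regions, counts) {
  if (nrow(regions) == 0L) {
    regions$support_control <- integer()
    regions$support_lbn <- integer()
    return(regions)
  }
  ridx <- rep.int(seq_len(nrow(regions)), lengths(regions$members))
  keys <- site_key(regions$chrom[ridx], unlist(regions$members))
  m <- match(keys, site_key(counts$chrom, counts$pos))
  ctl <- ifelse(is.na(m), 0L, counts$n_control[m])
  lbn <- ifelse(is.na(m), 0L, counts$n_lbn[m])
  regions$support_control <- as.integer(tapply(ctl, ridx, max))
  regions$support_lbn <- as.integer(tapply(lbn, ridx, max))
  regions
}

#' Call DMRs from per-individual DMS lists
#'
#' Convenience wrapper: sharing counts -> sharing filter -> merge ->
#' support annotation.
#'
#' @inheritParams sharing_counts
#' @inheritParams filter_shared
#' @inheritParams merge_sites
#' @return List with `regions`, `counts` (all shared-site counts),
#'   `shared` (sites passing the filter) and `histogram`.
#' @export
call_dmrs <- function(dms_by_individual, manifest, min_individuals = 2L,
                      rule = c("either", "both"), merge_gap = 100L) {
  counts <- sharing_counts(dms_by_individual, manifest)
  shared <- filter_shared(counts, min_individuals, match.arg(rule))
  regions <- region_support(merge_sites(shared, merge_gap), counts)
  list(regions = regions, counts = counts, shared = shared,
       histogram = sharing_histogram(counts))
}

#' Pooled methylation level of a region in one sample
#'
#' Count-weighted: 100 * (sum of methylated reads) / (sum of all reads)
#' over the sample's covered CpGs within `[start_pos, end_pos]`. With
#' `weighting = "mean"` the unweighted mean of per-CpG percentages is used
#' instead (sensitivity analysis).
#'
#' @param region One-row region data frame (or list) with `chrom`,
#'   `start_pos`, `end_pos`.
#' @param calls Methylation-call table of the sample.
#' @param weighting `"pooled"` (default) or `"mean"`.
#' @return Percentage in \[0, 100\], or `NA` if the sample covers no CpG in
#'   the region.
#' @export
region_methylation <- function(region, calls, weighting = c("pooled", "mean")) {
  weighting <- match.arg(weighting)
  hit <- calls$chrom == region$chrom &
    calls$pos >= region$start_pos & calls$pos <= region$end_pos
  if (!any(hit)) return(NA_real_)
  if (weighting == "pooled") {
    100 * sum(calls$meth[hit]) / sum(calls$meth[hit] + calls$unmeth[hit])
  } else {
    mean(methylation_percent(calls$meth[hit], calls$unmeth[hit]))
  }
}
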