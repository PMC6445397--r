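#' Read a Bismark-style coverage file of CpG methylation calls
#'
#' Parses the six-column tab-separated coverage dialect produced by
#' `bismark_methylation_extractor`: chromosome, start (1-based), end,
#' methylation percentage, methylated read count, unmethylated read count.
#' The percentage column is ignored; methylation levels are always recomputed
#' from the counts so that the definition is single-sourced. Rows are
#' re-sorted by (chrom, pos) if needed.
#'
#' @param path Path to the coverage file.
#' @param sample_id Optional sample identifier attached as an attribute.
#' @param merge_strands If `TRUE`, records at adjacent positions `pos` and
#'   `pos + 1` on the same chromosome (the two strands of one CpG dyad) are
#'   summed into a single record at the lower position. Off by default: the
#'   coverage dialect is normally already strand-collapsed.
#' @return A data frame with columns `chrom`, `pos` (1-based cytosine
#'   position), `meth` and `unmeth` (read counts), sorted by (chrom, pos),
#'   unique per position.
#' @export
read_coverage_file <- function(path, sample_id = NULL, merge_strands = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    tab <- methcalls()
    attr(tab, "sample_id") <- sample_id
    return(tab)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    stopf("malformed row in %s: expected 6 tab-separated fields, got %d at line %d",
          path, nf[which(nf != 6L)[1]], which(nf != 6L)[1])
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2L]))
  meth <- suppressWarnings(as.numeric(m[, 5L]))
  unmeth <- suppressWarnings(as.numeric(m[, 6L]))
  for (col in list(list(v = pos, name = "start"),
                   list(v = meth, name = "methylated count"),
                   list(v = unmeth, name = "unmethylated count"))) {
    bad <- which(is.na(col$v) | col$v != round(col$v))
    if (length(bad)) {
      stopf("non-integer %s in %s at line %d", col$name, path, bad[1])
    }
  }
  if (any(pos < 1)) stopf("position < 1 in %s at line %d", path, which(pos < 1)[1])
  if (any(meth < 0) || any(unmeth < 0)) {
    stopf("negative count in %s at line %d", path,
          which(meth < 0 | unmeth < 0)[1])
  }
  tab <- data.frame(chrom = m[, 1L], pos = as.integer(pos),
                    meth = as.integer(meth), unmeth = as.integer(unmeth),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  if (merge_strands) tab <- collapse_strands(tab)
  dup <- duplicated(site_key(tab$chrom, tab$pos))
  if (any(dup)) {
    i <- which(dup)[1]
    stopf("duplicate CpG record %s:%d in %s", tab$chrom[i], tab$pos[i], path)
  }
  attr(tab, "sample_id") <- sample_id
  tab
}

# Empty methylation-call table with the canonical columns.
methcalls <- function(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer()) {
  data.frame(chrom = chrom, pos = pos, meth = meth, unmeth = unmeth,
             stringsAsFactors = FALSE)
}

# Sum +/- strand records at (pos, pos + 1) into the lower position.
# Input must be sorted by (chrom, pos).
collapse_strands <- function(tab) {
  n <- nrow(tab)
  if (n < 2L) return(tab)
  adj <- which(tab$chrom[-n] == tab$chrom[-1] & tab$pos[-1] == tab$pos[-n] + 1L)
  if (length(adj) == 0L) return(tab)
  # first element of each run of adjacent pairs: merge greedily left-to-right
  adj <- adj[c(TRUE, diff(adj) > 1L)]
  tab$meth[adj] <- tab$meth[adj] + tab$meth[adj + 1L]
  tab$unmeth[adj] <- tab$unmeth[adj] + tab$unmeth[adj + 1L]
  tab <- tab[-(adj + 1L), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a methylation-call table in the coverage dialect
#'
#' Inverse of [read_coverage_file()]: writes the six-column tab-separated
#' format with the percentage recomputed from the counts (0 where coverage
#' is zero).
#'
#' @param calls Data frame with columns `chrom`, `pos`, `meth`, `unmeth`.
#' @param path Output path.
#' @export
write_coverage_file <- function(calls, path) {
  cov <- calls$meth + calls$unmeth
  pct <- ifelse(cov > 0, 100 * calls$meth / cov, 0)
  out <- data.frame(calls$chrom, calls$pos, calls$pos,
                    format(round(pct, 6), trim = TRUE, scientific = FALSE),
                    calls$meth, calls$unmeth)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and validate a sample manifest
#'
#' The manifest is a CSV with header columns `individual_id`, `age`
#' (`P2`/`P10`), `group` (`control`/`LBN`), `cohort`, and optionally `path`
#' (per-sample coverage file). Every individual must appear exactly twice,
#' once per age, with identical group and cohort in both rows.
#'
#' @param path Path to the manifest CSV.
#' @return The validated manifest data frame with an added `sample_id`
#'   column (`individual_id` and age joined by `_`).
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("individual_id", "age", "group", "cohort")
  missing <- setdiff(required, names(man))
  if (length(missing)) {
    stopf("manifest %s lacks required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  validate_manifest(man)
}

#' Validate a sample manifest data frame
#'
#' Enforces the pairing invariant (two rows per individual, one per age,
#' consistent group and cohort) and legal age/group values. Called by
#' [read_manifest()]; exported so in-memory manifests (e.g. from the
#' simulator) can be checked the same way.
#'
#' @param man Manifest data frame.
#' @return `man` with a `sample_id` column, invisibly validated.
#' @export
validate_manifest <- function(man) {
  bad_age <- setdiff(unique(man$age), c("P2", "P10"))
  if (length(bad_age)) stopf("unknown age value(s): %s", paste(bad_age, collapse = ", "))
  bad_grp <- setdiff(unique(man$group), c("control", "LBN"))
  if (length(bad_grp)) stopf("unknown group value(s): %s", paste(bad_grp, collapse = ", "))
  offenders <- character()
  for (id in unique(man$individual_id)) {
    rows <- man[man$individual_id == id, , drop = FALSE]
    ok <- nrow(rows) == 2L &&
      setequal(rows$age, c("P2", "P10")) &&
      length(unique(rows$group)) == 1L &&
      length(unique(rows$cohort)) == 1L
    if (!ok) offenders <- c(offenders, id)
  }
  if (length(offenders)) {
    stopf("manifest pairing violated for individual(s): %s",
          paste(offenders, collapse = ", "))
  }
  man$sample_id <- paste(man$individual_id, man$age, sep = "_")
  man
}

#' Export regions as a BED file
#'
#' Converts the package's 1-based inclusive region coordinates to BED's
#' 0-based half-open convention (`start = start_pos - 1`, `end = end_pos`).
#' The name column carries the region ID; the score column carries the
#' sharing count (the larger of the control and LBN support counts, 0 when
#' support has not been annotated).
#'
#' @param regions Region data frame from [merge_sites()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  score <- pmax(regions$support_control %||% 0L, regions$support_lbn %||% 0L)
  o <- order(regions$chrom, regions$start_pos)
  out <- data.frame(regions$chrom, regions$start_pos - 1L, regions$end_pos,
                    regions$region_id, score)[o, ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a methylation or delta matrix as TSV
#'
#' Regions as rows (ID in the first column), samples as columns with a
#' header row.
#'
#' @param values Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(values, path) {
  df <- data.frame(region_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path Path to the TSV.
#' @return Numeric matrix with region IDs as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
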