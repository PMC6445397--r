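#' Read gene models from a GTF file
#'
#' Imports `gene` and `exon` features (via rtracklayer). The TSS is the 5'
#' end by strand and the TTS the 3' end. When a GTF carries no `gene`
#' features, gene extents are derived as the range of each gene's exons.
#'
#' @param path Path to a GTF file with `gene_id` attributes.
#' @return Object of class `gene_models`: `genes` (data frame `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `tss`, `tts`) and `exons`
#'   (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gtf <- function(path) {
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  if (!"gene_id" %in% names(gr) || anyNA(gr$gene_id)) {
    stopf("GTF %s lacks a gene_id attribute on some features", path)
  }
  df <- data.frame(chrom = as.character(gr$seqnames),
                   start = gr$start, end = gr$end,
                   strand = as.character(gr$strand),
                   type = as.character(gr$type),
                   gene_id = gr$gene_id,
                   stringsAsFactors = FALSE)
  df$strand[df$strand == "*"] <- "+"
  exons <- unique(df[df$type == "exon",
                     c("gene_id", "chrom", "start", "end")])
  src <- df[df$type == "gene", , drop = FALSE]
  if (nrow(src) == 0L) src <- df[df$type == "exon", , drop = FALSE]
  if (nrow(src) == 0L) stopf("GTF %s contains no gene or exon features", path)
  # one row per gene_id: union extent, first strand/chrom
  ord <- order(src$gene_id)
  src <- src[ord, , drop = FALSE]
  genes <- do.call(rbind, lapply(split(src, src$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  genes$tts <- ifelse(genes$strand == "-", genes$start, genes$end)
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Classify regions by position relative to the nearest gene
#'
#' Homer-style annotation anchored at the region midpoint. The nearest gene
#' is the one minimizing |strand-oriented TSS distance| (ties broken by
#' lexicographic `gene_id`). Categories, checked in order: `promoter-TSS`
#' (midpoint within -1000..+100 bp of the TSS, transcription-oriented),
#' `TTS` (within -100..+1000 bp of the TTS), `exon` / `intron` (midpoint
#' inside the gene body), else `intergenic`. `tss_distance` is signed and
#' strand-oriented (positive = downstream of the TSS).
#'
#' @param regions Region data frame (`region_id`, `chrom`, `start_pos`,
#'   `end_pos`).
#' @param models A `gene_models` object from [read_gtf()].
#' @return Data frame `region_id`, `gene_id`, `category`, `tss_distance`.
#'   With an empty gene set every region is `intergenic` with `NA` gene.
#' @export
classify_region <- function(regions, models) {
  genes <- models$genes
  exons <- models$exons
  n <- nrow(regions)
  gene_id <- rep(NA_character_, n)
  category <- rep("intergenic", n)
  tss_distance <- rep(NA_real_, n)
  if (nrow(genes) > 0L) {
    for (i in seq_len(n)) {
      g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
      if (nrow(g) == 0L) next
      mid <- (regions$start_pos[i] + regions$end_pos[i]) %/% 2L
      d_tss <- ifelse(g$strand == "-", g$tss - mid, mid - g$tss)
      j <- order(abs(d_tss), g$gene_id)[1]
      gene_id[i] <- g$gene_id[j]
      tss_distance[i] <- d_tss[j]
      d_tts <- if (g$strand[j] == "-") g$tts[j] - mid else mid - g$tts[j]
      in_body <- mid >= g$start[j] & mid <= g$end[j]
      category[i] <- if (d_tss[j] >= -1000 && d_tss[j] <= 100) {
        "promoter-TSS"
      } else if (d_tts >= -100 && d_tts <= 1000) {
        "TTS"
      } else if (in_body) {
        ex <- exons[exons$gene_id == g$gene_id[j], , drop = FALSE]
        if (nrow(ex) > 0L && any(mid >= ex$start & mid <= ex$end)) "exon"
        else "intron"
      } else "intergenic"
    }
  }
  data.frame(region_id = regions$region_id, gene_id = gene_id,
             category = category, tss_distance = tss_distance,
             stringsAsFactors = FALSE)
}

#' Gene lists for a selected DMR set
#'
#' A (region, gene) association is retained iff its category is
#' `intergenic`, `promoter-TSS` or `TTS` with |TSS distance| <=
#' `max_tss_dist`, or its category is `exon` or `intron` (any distance).
#' Returns deduplicated, sorted gene lists for the positive- and
#' negative-loading region sets.
#'
#' @param selected A `dmr_selection` object.
#' @param associations Output of [classify_region()] covering the selected
#'   regions.
#' @param max_tss_dist Maximum |TSS distance| in bp for TSS-anchored
#'   categories (default 20000).
#' @return List with `positive_genes` and `negative_genes`.
#' @export
associate_genes <- function(selected, associations, max_tss_dist = 20000L) {
  keep <- !is.na(associations$gene_id) & (
    (associations$category %in% c("intergenic", "promoter-TSS", "TTS") &
       abs(associations$tss_distance) <= max_tss_dist) |
      associations$category %in% c("exon", "intron"))
  kept <- associations[keep, , drop = FALSE]
  list(positive_genes = sort(unique(
         kept$gene_id[kept$region_id %in% selected$positive_ids])),
       negative_genes = sort(unique(
         kept$gene_id[kept$region_id %in% selected$negative_ids])))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stopf("GMT %s: line %d has fewer than 3 fields", path, short[1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, the upper-tail hypergeometric probability
#' `P(X >= k)` of drawing `k` set members in `n = |gene_list|` draws from a
#' universe of `N` genes containing `K = |set in universe|` members,
#' Benjamini-Hochberg adjusted across sets; significant iff `q < alpha`.
#'
#' @param gene_list Character vector of query genes (subset of `universe`;
#'   genes outside it are dropped with a warning).
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Data frame `gene_set`, `set_size`, `overlap`, `p_value`,
#'   `q_value`, `significant`, ordered by p-value.
#' @export
hypergeometric_enrichment <- function(gene_list, gene_sets, universe,
                                      alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stopf("empty gene universe")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    gene_list <- intersect(gene_list, universe)
  }
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, gene_list))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(gene_set = nm, set_size = K, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha
  out <- out[order(out$p_value, out$gene_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
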