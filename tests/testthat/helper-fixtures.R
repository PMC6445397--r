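# Small in-code fixtures shared across test files.

calls_df <- function(pos, meth, unmeth, chrom = "chr1") {
  data.frame(chrom = rep(chrom, length.out = length(pos)), pos = as.integer(pos),
             meth = as.integer(meth), unmeth = as.integer(unmeth),
             stringsAsFactors = FALSE)
}

# Minimal two-individual manifest (one per group), already paired.
tiny_manifest <- function() {
  validate_manifest(data.frame(
    individual_id = rep(c("a1", "b1"), each = 2),
    age = rep(c("P2", "P10"), 2),
    group = rep(c("control", "LBN"), each = 2),
    cohort = c("1", "1", "2", "2"),
    stringsAsFactors = FALSE))
}

write_tiny_gtf <- function(path) {
  row_ <- function(chrom, type, start, end, strand, gene) {
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            chrom, type, start, end, strand, gene)
  }
  lines <- c(
    # plus-strand gene with two exons: TSS 10000, TTS 15000
    row_("chr1", "gene", 10000L, 15000L, "+", "geneA"),
    row_("chr1", "exon", 10000L, 10500L, "+", "geneA"),
    row_("chr1", "exon", 14000L, 15000L, "+", "geneA"),
    # minus-strand gene: TSS 80000 (right end), TTS 70000
    row_("chr1", "gene", 70000L, 80000L, "-", "geneB"),
    row_("chr1", "exon", 70000L, 80000L, "-", "geneB"),
    # distant plus-strand gene on chr2
    row_("chr2", "gene", 500000L, 510000L, "+", "geneC"),
    row_("chr2", "exon", 500000L, 510000L, "+", "geneC"))
  writeLines(lines, path)
  path
}

region_row <- function(chrom, start, end, id = sprintf("%s:%d-%d", chrom, start, end)) {
  data.frame(region_id = id, chrom = chrom, start_pos = as.integer(start),
             end_pos = as.integer(end), stringsAsFactors = FALSE)
}

# Cache for the expensive synthetic headline runs shared by several
# acceptance blocks (computed once per test session).
.headline_cache <- new.env(parent = emptyenv())

headline_runs <- function(n_seeds = 10) {
  key <- paste0("runs", n_seeds)
  if (is.null(.headline_cache[[key]])) {
    .headline_cache[[key]] <- lapply(seq_len(n_seeds), function(s) {
      experiment <- generate_experiment(simulation_config(seed = 100 + s))
      res <- suppressMessages(
        analyse_experiment(experiment$tables, experiment$manifest))
      list(aucs = res$aucs,
           n_regions = nrow(res$regions),
           recovery = evaluate_recovery(res$selected, res$regions,
                                        experiment$truth))
    })
  }
  .headline_cache[[key]]
}

null_runs <- function(n_seeds = 5) {
  key <- paste0("null", n_seeds)
  if (is.null(.headline_cache[[key]])) {
    .headline_cache[[key]] <- lapply(seq_len(n_seeds), function(s) {
      experiment <- generate_experiment(
        simulation_config(frac_exp = 0, seed = 200 + s))
      res <- suppressMessages(
        analyse_experiment(experiment$tables, experiment$manifest))
      list(aucs = res$aucs,
           recovery = evaluate_recovery(res$selected, res$regions,
                                        experiment$truth))
    })
  }
  .headline_cache[[key]]
}
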