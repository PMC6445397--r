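#' Run the full intra-individual methylation analysis in memory
#'
#' Stages: per-sample coverage filter; per-individual paired DMS test
#' (Fisher exact + BH within individual); sharing filter and 100-bp
#' coalescing into DMRs; DMR x sample percent matrix; cohort batch
#' correction followed by PCA of absolute levels; intra-individual
#' delta matrix (log2(P10/P2), from uncorrected percentages unless
#' `correct_delta`) and its PCA; per-component age and experience
#' separation AUCs; loading-threshold selection on the delta component
#' that best separates experience among the leading components.
#'
#' @param tables Named list of methylation-call tables covering every
#'   `manifest$sample_id`.
#' @param manifest Validated sample manifest.
#' @param min_coverage,fdr,min_diff,min_individuals,share_rule,merge_gap
#'   DMS/DMR parameters (defaults 10, 0.05, 0, 2, "either", 100).
#' @param max_missing_frac,epsilon Matrix parameters (defaults 0.2, 1).
#' @param loading_threshold Loading cutoff for DMR selection (default
#'   2.5e-2).
#' @param n_components Components to compute (default 10, capped at the
#'   available rank).
#' @param n_top_pcs How many leading components are scanned for the
#'   experience-separating delta component (default 5).
#' @param correct_delta Batch-correct the delta matrix too (default FALSE).
#' @param run_kmeans If TRUE, k-means cluster the corrected absolute matrix
#'   rows.
#' @param k,seed k-means parameters.
#' @param verbose Log per-stage counts with [message()].
#' @return List with per-stage outputs: `dms` (per-individual test
#'   results), `sharing` (counts + histogram), `regions`, `matrix`,
#'   `absolute_corrected`, `pca_absolute`, `delta`, `pca_delta`, `aucs`
#'   (`age_absolute`, `experience_absolute`, `experience_delta`),
#'   `separating_pc`, `selected`, optional `clusters`, and `params`.
#' @export
analyse_experiment <- function(tables, manifest, min_coverage = 10L,
                               fdr = 0.05, min_diff = 0,
                               min_individuals = 2L,
                               share_rule = c("either", "both"),
                               merge_gap = 100L, max_missing_frac = 0.2,
                               epsilon = 1, loading_threshold = 2.5e-2,
                               n_components = 10L, n_top_pcs = 5L,
                               correct_delta = FALSE, run_kmeans = FALSE,
                               k = 10L, seed = 1L, verbose = FALSE) {
  share_rule <- match.arg(share_rule)
  log_ <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  filtered <- lapply(tables, filter_coverage, min_coverage = min_coverage)

  individuals <- unique(manifest$individual_id)
  dms <- lapply(individuals, function(id) {
    paired_dms_test(filtered[[paste0(id, "_P2")]],
                    filtered[[paste0(id, "_P10")]],
                    fdr = fdr, min_diff = min_diff, individual_id = id)
  })
  names(dms) <- individuals
  n_dms <- vapply(dms, function(d) nrow(d$dms), integer(1))
  log_("DMS: %s sites tested per individual (median), %s significant (median)",
       stats::median(vapply(dms, function(d) nrow(d$tested), integer(1))),
       stats::median(n_dms))

  dmr_out <- call_dmrs(lapply(dms, `[[`, "dms"), manifest,
                       min_individuals = min_individuals, rule = share_rule,
                       merge_gap = merge_gap)
  regions <- dmr_out$regions
  log_("DMR: %d shared sites -> %d regions", nrow(dmr_out$shared),
       nrow(regions))
  if (nrow(regions) == 0L) {
    stopf("no DMRs called; consider lowering fdr or min_individuals")
  }

  mm <- build_matrix(regions, filtered, manifest,
                     max_missing_frac = max_missing_frac)
  log_("matrix: %d regions x %d samples (%d dropped)", nrow(mm$values),
       ncol(mm$values), mm$n_dropped)

  abs_corr <- remove_batch_effect(mm$values, mm$col_data$cohort)
  k_abs <- min(n_components, ncol(abs_corr), nrow(abs_corr))
  pca_abs <- run_pca(abs_corr, n_components = k_abs,
                     sample_metadata = mm$col_data)

  delta <- delta_methylation(mm$values, mm$col_data, epsilon = epsilon)
  delta_values <- if (correct_delta) {
    remove_batch_effect(delta$values, delta$col_data$cohort)
  } else delta$values
  k_del <- min(n_components, ncol(delta_values), nrow(delta_values))
  pca_del <- run_pca(delta_values, n_components = k_del,
                     sample_metadata = delta$col_data)
  log_("PCA: absolute EVR %s; delta EVR %s",
       paste(sprintf("%.2f", utils::head(pca_abs$explained_variance_ratio, 3)),
             collapse = "/"),
       paste(sprintf("%.2f", utils::head(pca_del$explained_variance_ratio, 3)),
             collapse = "/"))

  aucs <- list(
    age_absolute = separation_score(pca_abs$scores,
                                    mm$col_data$age == "P10"),
    experience_absolute = separation_score(pca_abs$scores,
                                           mm$col_data$group == "LBN"),
    experience_delta = separation_score(pca_del$scores,
                                        delta$col_data$group == "LBN"))

  top <- seq_len(min(n_top_pcs, ncol(pca_del$scores)))
  separating_pc <- top[which.max(aucs$experience_delta[top])]
  selected <- select_by_loading(pca_del, separating_pc,
                                threshold = loading_threshold)
  log_("selection: PC%d, %d positive / %d negative regions", separating_pc,
       length(selected$positive_ids), length(selected$negative_ids))

  clusters <- if (run_kmeans) kmeans_rows(abs_corr, k = k, seed = seed)
              else NULL

  list(dms = dms, sharing = dmr_out[c("counts", "shared", "histogram")],
       regions = regions, matrix = mm, absolute_corrected = abs_corr,
       pca_absolute = pca_abs, delta = delta, delta_values = delta_values,
       pca_delta = pca_del, aucs = aucs, separating_pc = separating_pc,
       selected = selected, clusters = clusters,
       params = list(min_coverage = min_coverage, fdr = fdr,
                     min_diff = min_diff, min_individuals = min_individuals,
                     share_rule = share_rule, merge_gap = merge_gap,
                     max_missing_frac = max_missing_frac, epsilon = epsilon,
                     loading_threshold = loading_threshold,
                     n_components = n_components, n_top_pcs = n_top_pcs,
                     correct_delta = correct_delta, k = k, seed = seed))
}

#' Run the pipeline end to end and write all artifacts
#'
#' Orchestrates simulate/load -> DMS -> DMR -> matrices -> PCA -> selection
#' -> (optional) gene annotation and enrichment, writing every stage's
#' output under `out_dir` together with a JSON run manifest echoing all
#' parameters and stage counts. Identical inputs and seeds reproduce all
#' output files.
#'
#' @param out_dir Output directory (created).
#' @param manifest_path Path to a manifest CSV whose `path` column points
#'   at per-sample coverage files; ignored when `sim_config` is given.
#' @param sim_config Optional `sim_config`: simulate instead of loading.
#' @param gtf,gmt Optional annotation inputs; enrichment requires both.
#' @param ... Parameters forwarded to [analyse_experiment()].
#' @return Invisibly, the [analyse_experiment()] result list, augmented
#'   with `truth`/`recovery` (simulated runs) and `associations`,
#'   `gene_lists`, `enrichment` when annotation inputs are given.
#' @export
run_pipeline <- function(out_dir, manifest_path = NULL, sim_config = NULL,
                         gtf = NULL, gmt = NULL, ...) {
  if (!is.null(gmt) && is.null(gtf)) {
    stopf("enrichment (gmt) requires a gene annotation (gtf)")
  }
  if (!is.null(gtf) && !file.exists(gtf)) stopf("GTF not found: %s", gtf)
  if (!is.null(gmt) && !file.exists(gmt)) stopf("GMT not found: %s", gmt)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(sim_config)) {
    experiment <- generate_experiment(sim_config)
    tables <- experiment$tables
    manifest <- experiment$manifest
    truth <- experiment$truth
  } else if (!is.null(manifest_path)) {
    manifest <- read_manifest(manifest_path)
    if (!"path" %in% names(manifest)) {
      stopf("manifest must carry a path column naming coverage files")
    }
    tables <- lapply(seq_len(nrow(manifest)), function(i) {
      read_coverage_file(manifest$path[i], sample_id = manifest$sample_id[i])
    })
    names(tables) <- manifest$sample_id
    truth <- NULL
  } else {
    stopf("either manifest_path or sim_config is required")
  }

  res <- analyse_experiment(tables, manifest, ...)

  write_regions_bed(res$regions, file.path(out_dir, "dmrs.bed"))
  utils::write.table(res$sharing$histogram,
                     file.path(out_dir, "sharing_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dms_all <- do.call(rbind, lapply(res$dms, `[[`, "tested"))
  utils::write.table(dms_all, file.path(out_dir, "dms_tested.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(res$matrix$values, file.path(out_dir, "methylation_matrix.tsv"))
  utils::write.table(res$matrix$col_data,
                     file.path(out_dir, "sample_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(res$delta_values, file.path(out_dir, "delta_matrix.tsv"))
  for (what in c("absolute", "delta")) {
    pca <- res[[paste0("pca_", what)]]
    write_matrix_tsv(t(pca$scores), file.path(out_dir, paste0("pca_", what, "_scores.tsv")))
    lm_ <- pca$loadings; rownames(lm_) <- pca$feature_ids
    write_matrix_tsv(lm_, file.path(out_dir, paste0("pca_", what, "_loadings.tsv")))
  }
  sel <- res$selected
  sel_df <- data.frame(region_id = c(sel$positive_ids, sel$negative_ids),
                       sign = rep(c("positive", "negative"),
                                  c(length(sel$positive_ids),
                                    length(sel$negative_ids))),
                       stringsAsFactors = FALSE)
  utils::write.table(sel_df, file.path(out_dir, "selected_dmrs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(truth)) {
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res$truth <- truth
    res$recovery <- evaluate_recovery(res$selected, res$regions, truth)
  }

  if (!is.null(gtf)) {
    models <- read_gtf(gtf)
    assoc <- classify_region(res$regions, models)
    utils::write.table(assoc, file.path(out_dir, "gene_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$associations <- assoc
    res$gene_lists <- associate_genes(res$selected, assoc)
    if (!is.null(gmt)) {
      sets <- read_gmt(gmt)
      universe <- models$genes$gene_id
      res$enrichment <- lapply(res$gene_lists, function(gl) {
        hypergeometric_enrichment(gl, sets, universe)
      })
      for (nm in names(res$enrichment)) {
        utils::write.table(res$enrichment[[nm]],
                           file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  run_manifest <- c(res$params, list(
    n_individuals = length(unique(manifest$individual_id)),
    n_samples = nrow(manifest),
    n_dms_per_individual = vapply(res$dms, function(d) nrow(d$dms), integer(1)),
    n_shared_sites = nrow(res$sharing$shared),
    n_regions = nrow(res$regions),
    matrix_dim = dim(res$matrix$values),
    explained_variance_absolute = res$pca_absolute$explained_variance_ratio,
    explained_variance_delta = res$pca_delta$explained_variance_ratio,
    separating_pc = res$separating_pc,
    n_selected_positive = length(sel$positive_ids),
    n_selected_negative = length(sel$negative_ids)))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
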