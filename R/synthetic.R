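#' Configuration for the paired-RRBS simulator
#'
#' Encodes the study design being emulated: 19 individuals in two cohorts
#' (cohort 1: 6 control + 5 LBN; cohort 2: 4 control + 4 LBN), each sampled
#' at P2 and P10, with per-CpG methylation driven on the logit scale by a
#' baseline, a per-individual random effect shared across the two ages, an
#' age effect at P10, an experience effect at P10 in LBN individuals only,
#' and a cohort (batch) effect. Read counts are beta-binomial given a
#' shifted-Poisson coverage.
#'
#' @param n_cpgs Number of CpGs on the single synthetic chromosome.
#' @param mean_spacing Mean exponential gap between CpGs in bp.
#' @param cohort_sizes List of per-cohort `c(control = , lbn = )` counts.
#' @param coverage_mean Mean read coverage (shifted Poisson, minimum 1).
#' @param baseline_logit_sd SD of the per-CpG baseline logit methylation
#'   (mean 0, i.e. 50%).
#' @param indiv_sd SD of the per-(individual, CpG) random effect shared
#'   across the two ages of an individual.
#' @param frac_age,frac_exp Fractions of CpGs carrying an age /
#'   experience effect (disjoint sets; `frac_age + frac_exp <= 1`).
#' @param age_effect_logit,exp_effect_logit Effect magnitudes on the logit
#'   scale (random sign per CpG). Effects act only at P10; the experience
#'   effect only in LBN individuals.
#' @param cohort_effect_logit SD of the per-CpG cohort-2 offset.
#' @param overdispersion_rho Beta-binomial intra-class correlation
#'   (0 recovers binomial counts).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return Validated list of class `sim_config`.
#' @export
simulation_config <- function(n_cpgs = 20000L, mean_spacing = 300,
                              cohort_sizes = list(c(control = 6L, lbn = 5L),
                                                  c(control = 4L, lbn = 4L)),
                              coverage_mean = 30, baseline_logit_sd = 1.5,
                              indiv_sd = 0.8, frac_age = 0.05,
                              age_effect_logit = 1.5, frac_exp = 0.02,
                              exp_effect_logit = 1.2,
                              cohort_effect_logit = 0.3,
                              overdispersion_rho = 0.05, seed = 1L) {
  cfg <- list(n_cpgs = as.integer(n_cpgs), mean_spacing = mean_spacing,
              cohort_sizes = cohort_sizes, coverage_mean = coverage_mean,
              baseline_logit_sd = baseline_logit_sd, indiv_sd = indiv_sd,
              frac_age = frac_age, age_effect_logit = age_effect_logit,
              frac_exp = frac_exp, exp_effect_logit = exp_effect_logit,
              cohort_effect_logit = cohort_effect_logit,
              overdispersion_rho = overdispersion_rho,
              seed = as.integer(seed))
  if (cfg$n_cpgs < 1) stopf("n_cpgs must be >= 1")
  if (cfg$frac_age < 0 || cfg$frac_exp < 0 ||
      cfg$frac_age + cfg$frac_exp > 1) {
    stopf("effect fractions must be non-negative with frac_age + frac_exp <= 1")
  }
  for (f in c("baseline_logit_sd", "indiv_sd", "age_effect_logit",
              "exp_effect_logit", "cohort_effect_logit")) {
    if (cfg[[f]] < 0) stopf("%s must be >= 0", f)
  }
  if (cfg$overdispersion_rho < 0 || cfg$overdispersion_rho >= 1) {
    stopf("overdispersion_rho must lie in [0, 1)")
  }
  if (cfg$coverage_mean < 1) stopf("coverage_mean must be >= 1")
  structure(cfg, class = "sim_config")
}

# Manifest implied by the cohort layout of a sim_config.
sim_manifest <- function(cfg) {
  rows <- list()
  i <- 0L
  for (co in seq_along(cfg$cohort_sizes)) {
    sizes <- cfg$cohort_sizes[[co]]
    for (grp in c("control", "LBN")) {
      n <- unname(sizes[[if (grp == "control") "control" else "lbn"]])
      for (r in seq_len(n)) {
        i <- i + 1L
        rows[[i]] <- data.frame(individual_id = sprintf("ind%02d", i),
                                group = grp, cohort = as.character(co),
                                stringsAsFactors = FALSE)
      }
    }
  }
  ind <- do.call(rbind, rows)
  man <- rbind(transform(ind, age = "P2"), transform(ind, age = "P10"))
  man <- man[order(man$individual_id, man$age != "P2"), , drop = FALSE]
  rownames(man) <- NULL
  validate_manifest(man[, c("individual_id", "age", "group", "cohort")])
}

#' Generate a paired-timepoint RRBS experiment with ground truth
#'
#' Simulates per-sample CpG methylation-call tables under the logit model
#' `logit p = mu_j + u_ij + alpha_j I(P10) + beta_j I(P10 & LBN) +
#' gamma_j I(cohort 2)`, with coverage `1 + Poisson(coverage_mean - 1)` and
#' beta-binomial methylated counts. The per-individual effect `u_ij` is
#' shared between the two ages of an individual, so it cancels in the
#' intra-individual delta while inflating inter-individual variance of
#' absolute levels. Age and experience effects land on disjoint CpG sets.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List with `tables` (named per-sample call tables over identical
#'   positions), `manifest` (valid paired manifest), `truth` (per-CpG
#'   `chrom`, `pos`, `effect_class` in null/age/experience, `mu`, `alpha`,
#'   `beta`, `gamma`) and the `config`.
#' @export
generate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_cpgs
    gaps <- pmax(2, round(stats::rexp(n, 1 / cfg$mean_spacing)))
    pos <- as.integer(1000 + cumsum(gaps))
    chrom <- rep("chrS", n)
    n_age <- round(cfg$frac_age * n)
    n_exp <- round(cfg$frac_exp * n)
    hit <- sample.int(n, n_age + n_exp)
    age_idx <- hit[seq_len(n_age)]
    exp_idx <- hit[n_age + seq_len(n_exp)]
    alpha <- numeric(n)
    alpha[age_idx] <- cfg$age_effect_logit * sample(c(-1, 1), n_age, TRUE)
    beta <- numeric(n)
    beta[exp_idx] <- cfg$exp_effect_logit * sample(c(-1, 1), n_exp, TRUE)
    gamma <- stats::rnorm(n, 0, cfg$cohort_effect_logit)
    mu <- stats::rnorm(n, 0, cfg$baseline_logit_sd)
    effect_class <- rep("null", n)
    effect_class[age_idx] <- "age"
    effect_class[exp_idx] <- "experience"
    manifest <- sim_manifest(cfg)
    tables <- list()
    for (id in unique(manifest$individual_id)) {
      info <- manifest[manifest$individual_id == id, ][1, ]
      u <- stats::rnorm(n, 0, cfg$indiv_sd)
      for (age in c("P2", "P10")) {
        eta <- mu + u + gamma * (info$cohort == "2")
        if (age == "P10") {
          eta <- eta + alpha + beta * (info$group == "LBN")
        }
        p <- stats::plogis(eta)
        cov <- 1L + stats::rpois(n, cfg$coverage_mean - 1)
        if (cfg$overdispersion_rho > 0) {
          s <- (1 - cfg$overdispersion_rho) / cfg$overdispersion_rho
          pb <- stats::rbeta(n, p * s, (1 - p) * s)
          pb[is.na(pb)] <- p[is.na(pb)]  # numerically degenerate shapes
        } else {
          pb <- p
        }
        meth <- stats::rbinom(n, cov, pb)
        tables[[paste(id, age, sep = "_")]] <-
          data.frame(chrom = chrom, pos = pos, meth = meth,
                     unmeth = cov - meth, stringsAsFactors = FALSE)
      }
    }
    truth <- data.frame(chrom = chrom, pos = pos,
                        effect_class = effect_class, mu = mu, alpha = alpha,
                        beta = beta, gamma = gamma, stringsAsFactors = FALSE)
    list(tables = tables, manifest = manifest, truth = truth, config = cfg)
  })
}

#' Write a simulated experiment to disk
#'
#' Coverage files in the Bismark dialect (one per sample), a manifest CSV
#' whose `path` column points at them, and the truth table as TSV.
#'
#' @param experiment Output of [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- experiment$manifest
  man$path <- file.path(dir, paste0(man$sample_id, ".cov"))
  for (i in seq_len(nrow(man))) {
    write_coverage_file(experiment$tables[[man$sample_id[i]]], man$path[i])
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man[, c("individual_id", "age", "group", "cohort", "path")],
                   manifest_path, row.names = FALSE, quote = FALSE)
  utils::write.table(experiment$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest_path)
}

#' Precision and recall of a DMR selection for experience effects
#'
#' A selected region is a true positive if at least one member CpG carries
#' an experience effect in the ground truth. Precision is TP over selected
#' regions (`NA` for an empty selection); recall is selected-TP over all
#' regions containing an experience CpG. The base rate (fraction of all
#' regions containing an experience CpG) is reported for reference.
#'
#' @param selected A `dmr_selection` (positive and negative sets pooled).
#' @param regions Region data frame with `members` list-column.
#' @param truth Truth table from [generate_experiment()].
#' @return List `precision`, `recall`, `base_rate`, `n_selected`,
#'   `n_experience_regions`.
#' @export
evaluate_recovery <- function(selected, regions, truth) {
  exp_keys <- site_key(truth$chrom, truth$pos)[truth$effect_class == "experience"]
  has_exp <- vapply(seq_len(nrow(regions)), function(i) {
    any(site_key(regions$chrom[i], regions$members[[i]]) %in% exp_keys)
  }, logical(1))
  sel_ids <- union(selected$positive_ids, selected$negative_ids)
  is_sel <- regions$region_id %in% sel_ids
  tp <- sum(is_sel & has_exp)
  n_exp <- sum(has_exp)
  list(precision = if (sum(is_sel) > 0) tp / sum(is_sel) else NA_real_,
       recall = if (n_exp > 0) tp / n_exp else NA_real_,
       base_rate = if (nrow(regions) > 0) n_exp / nrow(regions) else NA_real_,
       n_selected = sum(is_sel), n_experience_regions = n_exp)
}
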