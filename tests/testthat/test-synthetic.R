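test_that("simulation config validates its fields", {
  cfg <- simulation_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_cpgs, 20000L)
  expect_error(simulation_config(frac_age = 0.7, frac_exp = 0.5), "frac")
  expect_error(simulation_config(overdispersion_rho = 1), "rho")
  expect_error(simulation_config(indiv_sd = -1), "indiv_sd")
})

test_that("the generated design matches the two-cohort study layout", {
  cfg <- simulation_config(n_cpgs = 500, seed = 4)
  experiment <- generate_experiment(cfg)
  man <- experiment$manifest
  expect_equal(nrow(man), 38L)
  expect_equal(length(unique(man$individual_id)), 19L)
  tab <- table(man$group[man$age == "P2"], man$cohort[man$age == "P2"])
  expect_equal(unname(tab["control", ]), c(6L, 4L))
  expect_equal(unname(tab["LBN", ]), c(5L, 4L))
  # every sample covers the identical position set; counts are sane
  pos <- experiment$tables[[1]]$pos
  for (t in experiment$tables) {
    expect_identical(t$pos, pos)
    expect_true(all(t$meth >= 0 & t$unmeth >= 0))
    expect_true(all(t$meth + t$unmeth >= 1))
  }
  # truth classes match the configured fractions exactly (rounded)
  expect_equal(sum(experiment$truth$effect_class == "age"),
               round(0.05 * 500))
  expect_equal(sum(experiment$truth$effect_class == "experience"),
               round(0.02 * 500))
  # effects on disjoint sets, acting where declared
  expect_true(all(experiment$truth$alpha[experiment$truth$effect_class != "age"] == 0))
  expect_true(all(experiment$truth$beta[experiment$truth$effect_class != "experience"] == 0))
})

test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cfg <- simulation_config(n_cpgs = 200, seed = 77)
  e1 <- generate_experiment(cfg)
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$tables, e2$tables)
  expect_identical(e1$truth, e2$truth)
  expect_equal(rnorm(1), before)   # caller RNG stream undisturbed
  e3 <- generate_experiment(simulation_config(n_cpgs = 200, seed = 78))
  expect_false(identical(e1$tables, e3$tables))
})

test_that("noise-free high-coverage means converge to the logistic baseline", {
  cfg <- simulation_config(n_cpgs = 300, coverage_mean = 500,
                           baseline_logit_sd = 1.5, indiv_sd = 0,
                           frac_age = 0, frac_exp = 0,
                           cohort_effect_logit = 0, overdispersion_rho = 0,
                           seed = 6)
  experiment <- generate_experiment(cfg)
  pct <- sapply(experiment$tables, function(t)
    methylation_percent(t$meth, t$unmeth))
  expect_equal(rowMeans(pct), 100 * plogis(experiment$truth$mu),
               tolerance = 2, ignore_attr = TRUE)   # percentage points
})

test_that("written experiments read back through the standard io path", {
  cfg <- simulation_config(n_cpgs = 60, seed = 9)
  experiment <- generate_experiment(cfg)
  dir <- withr::local_tempdir()
  manifest_path <- write_experiment(experiment, dir)
  man <- read_manifest(manifest_path)
  expect_equal(nrow(man), 38L)
  back <- read_coverage_file(man$path[1])
  expect_equal(back[c("chrom", "pos", "meth", "unmeth")],
               experiment$tables[[man$sample_id[1]]], ignore_attr = TRUE)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 60L)
})

test_that("recovery scoring counts regions containing experience CpGs", {
  truth <- data.frame(chrom = "chrS", pos = c(10L, 50L, 200L, 400L),
                      effect_class = c("experience", "null", "experience", "null"),
                      stringsAsFactors = FALSE)
  regions <- merge_sites(truth[c("chrom", "pos")], merge_gap = 100)
  # regions: {10,50}, {200}, {400}; two contain experience CpGs
  sel_all <- structure(list(positive_ids = regions$region_id[1:2],
                            negative_ids = character(0)),
                       class = "dmr_selection")
  rec <- evaluate_recovery(sel_all, regions, truth)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  expect_equal(rec$base_rate, 2 / 3)

  empty <- structure(list(positive_ids = character(0),
                          negative_ids = character(0)),
                     class = "dmr_selection")
  rec0 <- evaluate_recovery(empty, regions, truth)
  expect_true(is.na(rec0$precision))
  expect_equal(rec0$recall, 0)
})

test_that("random selections recover precision at the base rate on average", {
  set.seed(61)
  truth <- data.frame(chrom = "chrS",
                      pos = as.integer(seq(1, by = 200, length.out = 200)),
                      effect_class = sample(c("experience", "null"), 200,
                                            replace = TRUE, prob = c(0.15, 0.85)),
                      stringsAsFactors = FALSE)
  regions <- merge_sites(truth[c("chrom", "pos")], merge_gap = 100)
  base <- mean(truth$effect_class == "experience")
  prec <- replicate(1000, {
    ids <- sample(regions$region_id, 50)
    sel <- structure(list(positive_ids = ids, negative_ids = character(0)),
                     class = "dmr_selection")
    evaluate_recovery(sel, regions, truth)$precision
  })
  # Monte-Carlo error of the mean ~ sqrt(base*(1-base)/50)/sqrt(1000)
  expect_equal(mean(prec), base, tolerance = 0.02)
})
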