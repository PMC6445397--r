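dms_of <- function(pos, chrom = "chr1") {
  data.frame(chrom = rep(chrom, length.out = length(pos)),
             pos = as.integer(pos), stringsAsFactors = FALSE)
}

four_ind_manifest <- function() {
  validate_manifest(data.frame(
    individual_id = rep(c("c1", "c2", "l1", "l2"), each = 2),
    age = rep(c("P2", "P10"), 4),
    group = rep(c("control", "control", "LBN", "LBN"), each = 2),
    cohort = "1", stringsAsFactors = FALSE))
}

test_that("sharing counts tally distinct individuals per group", {
  man <- four_ind_manifest()
  counts <- sharing_counts(list(c1 = dms_of(c(100, 200)),
                                c2 = dms_of(100),
                                l1 = dms_of(c(100, 300)),
                                l2 = dms_of(integer(0))), man)
  expect_equal(counts$pos, c(100L, 200L, 300L))
  expect_equal(counts$n_control, c(2L, 1L, 0L))
  expect_equal(counts$n_lbn, c(1L, 0L, 1L))

  hist <- sharing_histogram(counts)
  expect_equal(hist$n_sharing, c(1L, 3L))
  expect_equal(hist$n_sites, c(2L, 1L))

  empty <- sharing_counts(list(c1 = dms_of(integer(0))), man)
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(sharing_histogram(empty)), 0L)
})

test_that("sharing filter applies the either/both group rule", {
  counts <- data.frame(chrom = "chr1", pos = 1:4,
                       n_control = c(2L, 1L, 0L, 2L),
                       n_lbn = c(0L, 1L, 2L, 2L))
  expect_equal(filter_shared(counts, 2)$pos, c(1L, 3L, 4L))   # (1,1) dropped
  expect_equal(filter_shared(counts, 2, rule = "both")$pos, 4L)
  expect_equal(nrow(filter_shared(counts, 1)), 4L)
  expect_error(filter_shared(counts, 0), "min_individuals")
})

test_that("site merging chains within the gap and never spans chromosomes", {
  r <- merge_sites(dms_of(c(100, 150, 260, 400)), merge_gap = 100)
  expect_equal(r$region_id, c("chr1:100-150", "chr1:260-260", "chr1:400-400"))
  expect_equal(r$n_sites, c(2L, 1L, 1L))
  expect_equal(r$members[[1]], c(100L, 150L))

  # transitive chaining, inclusive at exactly the gap
  r2 <- merge_sites(dms_of(c(100, 200, 300)), merge_gap = 100)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$members[[1]], c(100L, 200L, 300L))

  r3 <- merge_sites(dms_of(500))
  expect_equal(r3$region_id, "chr1:500-500")

  sites <- rbind(dms_of(c(10, 50), "chr2"), dms_of(c(10, 50), "chr1"))
  r4 <- merge_sites(sites, merge_gap = 100)
  expect_equal(r4$chrom, c("chr1", "chr2"))
})

test_that("merging is idempotent, order-invariant, and gap-lawful", {
  set.seed(11)
  for (i in 1:100) {
    pos <- sort(sample(1:5000, sample(2:60, 1)))
    sites <- dms_of(pos)
    r <- merge_sites(sites, merge_gap = 100)
    # within-region gaps <= 100; between consecutive regions > 100
    for (j in seq_len(nrow(r))) {
      if (r$n_sites[j] > 1) expect_lte(max(diff(r$members[[j]])), 100)
      if (j > 1) expect_gt(r$start_pos[j] - r$end_pos[j - 1], 100)
    }
    # idempotent on its own member sites
    again <- merge_sites(dms_of(unlist(r$members)), merge_gap = 100)
    expect_equal(again$region_id, r$region_id)
    # invariant to input order
    shuf <- merge_sites(sites[sample(nrow(sites)), ], merge_gap = 100)
    expect_equal(shuf$region_id, r$region_id)
  }
})

test_that("region count is monotone non-increasing in the merge gap", {
  set.seed(5)
  pos <- sort(sample(1:3000, 80))
  n_regions <- vapply(c(10, 50, 100, 200, 500),
                      function(g) nrow(merge_sites(dms_of(pos), g)), integer(1))
  expect_true(all(diff(n_regions) <= 0))
})

test_that("region support records the max sharing per group over member sites", {
  man <- four_ind_manifest()
  counts <- sharing_counts(list(c1 = dms_of(c(100, 150)), c2 = dms_of(100),
                                l1 = dms_of(150), l2 = dms_of(150)), man)
  out <- call_dmrs(list(c1 = dms_of(c(100, 150)), c2 = dms_of(100),
                        l1 = dms_of(150), l2 = dms_of(150)), man,
                   min_individuals = 2)
  expect_equal(nrow(out$regions), 1L)
  expect_equal(out$regions$support_control, 2L)
  expect_equal(out$regions$support_lbn, 2L)
  expect_equal(counts$n_control, c(2L, 1L))
})

test_that("region methylation pools reads and bounds hold", {
  region <- region_row("chr1", 100, 200)
  tab <- calls_df(c(100, 150), c(5, 10), c(5, 0))
  expect_equal(region_methylation(region, tab), 75)
  # single-CpG region reduces to the site percent
  expect_equal(region_methylation(region_row("chr1", 100, 100), tab),
               methylation_percent(5, 5))
  # no covered CpG -> missing
  expect_true(is.na(region_methylation(region_row("chr2", 100, 200), tab)))
  # pooled value lies between the per-site percent extremes
  set.seed(2)
  for (i in 1:20) {
    t2 <- calls_df(seq(100, 190, 10), rpois(10, 5), rpois(10, 5))
    t2 <- t2[t2$meth + t2$unmeth > 0, ]
    v <- region_methylation(region, t2)
    pct <- methylation_percent(t2$meth, t2$unmeth)
    expect_gte(v, min(pct) - 1e-12)
    expect_lte(v, max(pct) + 1e-12)
  }
  # mean-of-percent variant
  expect_equal(region_methylation(region, tab, weighting = "mean"),
               mean(c(50, 100)))
})
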