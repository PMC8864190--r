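seg_df <- function(chrom, start, end, cn) {
  data.frame(chrom = chrom, start = start, end = end, cn = as.integer(cn),
             stringsAsFactors = FALSE)
}

test_that("overlap matching follows the truth-fraction rule", {
  ## 80 kb overlap on a 140 kb truth segment (~57%) validates the call
  det <- seg_df("chr1", 100e3, 200e3, 3)
  tru <- seg_df("chr1", 120e3, 260e3, 3)
  m <- match_cnvs(det, tru)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  ## below 50% of the truth length: no match
  tru2 <- seg_df("chr1", 120e3, 400e3, 3)
  m2 <- match_cnvs(det, tru2)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))
  ## direction-aware: a loss call never validates a gain
  m3 <- match_cnvs(seg_df("chr1", 100e3, 200e3, 1), tru)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0L, 1L, 1L))
  ## empty detected, identity, overlapping truth
  m4 <- match_cnvs(det[0, ], do.call(rbind, lapply(1:20, function(i)
    seg_df("chr1", i * 1e6, i * 1e6 + 5e5, 3))))
  expect_equal(c(m4$tp, m4$fp, m4$fn), c(0L, 0L, 20L))
  m5 <- match_cnvs(tru, tru)
  expect_equal(c(m5$tp, m5$fp, m5$fn), c(1L, 0L, 0L))
  expect_error(match_cnvs(det, rbind(tru, tru)), "overlap")
})

test_that("matching agrees with brute-force interval arithmetic", {
  ## 1000 random single-interval pairs, three matching modes
  for (case in 1:1000) {
    v <- withr::with_seed(case, round(runif(4, 0, 1e6)))
    d <- seg_df("chr1", min(v[1], v[2]), max(v[1], v[2]) + 1, 3)
    t <- seg_df("chr1", min(v[3], v[4]), max(v[3], v[4]) + 1, 3)
    ov <- oracle_overlap(d$start, d$end, t$start, t$end)
    expect_equal(match_cnvs(d, t)$tp,
                 as.integer(ov >= 0.5 * (t$end - t$start)))
    expect_equal(match_cnvs(d, t, min_overlap = 0)$tp, as.integer(ov > 0))
    expect_equal(match_cnvs(d, t, mode = "reciprocal")$tp,
                 as.integer(ov > 0 && ov >= 0.5 * (t$end - t$start) &&
                              ov >= 0.5 * (d$end - d$start)))
  }
})

test_that("each truth segment validates at most one call", {
  tru <- seg_df("chr1", 0, 1e6, 3)
  det <- seg_df(rep("chr1", 2), c(0, 5e5), c(5.5e5, 1e6), 3)
  m <- match_cnvs(det, tru)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 1L, 0L))
  expect_equal(m$matched_pairs$overlap, 5.5e5) # greedy by descending overlap
})

test_that("sensitivity and FDR formulas handle undefined denominators", {
  a <- accuracy_metrics(structure(list(tp = 16, fn = 4, fp = 0), class = "match_result"))
  expect_equal(a$sensitivity, 0.80)
  expect_equal(a$fdr, 0)
  b <- accuracy_metrics(structure(list(tp = 0, fn = 0, fp = 0), class = "match_result"))
  expect_true(is.na(b$sensitivity))
  expect_true(is.na(b$fdr))
})

test_that("a noiseless cell recovers every large spiked CNV", {
  g <- synthetic_genome_hg19(scale = 0.25, seed = 30)
  truth <- spike_random_cnvs(g, 15e6 * 0.25, 20, seed = 31)
  clean <- noise_model() # Poisson only, no GC bias, no duplicates
  cell <- simulate_cell_reads(g, truth, 3e5, clean, seed = 32, cell_id = "c")
  res <- call_cell(cell, make_bins(g, 5000), seed = 33)
  m <- match_cnvs(extract_cnv_calls(res$cn), truth$segments)
  expect_equal(accuracy_metrics(m)$sensitivity, 1.0)
})

test_that("saturation analysis handles flat cells and reaches 1 at full depth", {
  g <- build_genome(4, 2e7, seed = 40)
  nm <- noise_model() # Poisson only: a diploid cell stays call-free
  ## diploid truth: no abnormal bins at full depth
  flat <- simulate_cell_reads(g, clone_profile("d"), 2.5e5, nm, seed = 41,
                              cell_id = "flat")
  expect_warning(
    sc <- saturation_analysis(flat, g, schedule = c(5e4, 1e5, 2e5),
                              n_bins = 400, seed = 42),
    "no abnormal bins"
  )
  expect_true(is.na(sc$saturation_point))
  ## an aneuploid cell: self-comparison at full depth gives fraction 1
  aneu <- clone_profile("a", cnv_segments(c("chr1", "chr3"), c(2e6, 5e6),
                                          c(10e6, 15e6), c(3, 1)))
  cell <- simulate_cell_reads(g, aneu, 2.1e5, nm, seed = 43, cell_id = "c")
  n_unique <- sum(!duplicated(paste(cell$chrom, cell$start)))
  sc2 <- saturation_analysis(cell, g, schedule = c(2e4, 5e4, 1e5, n_unique),
                             n_bins = 400, seed = 44)
  expect_equal(sc2$detected_fraction[length(sc2$detected_fraction)], 1.0)
  expect_true(all(diff(sc2$smoothed_fraction) >= 0))
  expect_lte(sc2$saturation_point, 2e5)
  ## truncation warning when the schedule exceeds the available reads
  expect_warning(
    saturation_analysis(cell, g, schedule = c(1e5, 5e5), n_bins = 400, seed = 45),
    "truncating"
  )
})
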