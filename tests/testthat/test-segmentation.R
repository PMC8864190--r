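test_that("constant profiles stay a single segment per chromosome", {
  bins <- fake_bins(300, chrom = c("chr1", "chr2", "chr3"))
  sp <- cbs_segment(fake_ratio_profile(rep(1, 300)), bins, seed = 1)
  expect_equal(nrow(sp$segments), 3L)
  expect_equal(sp$segments$mean_ratio, rep(1, 3))
  expect_equal(sum(sp$segments$n_bins), 300L)
})

test_that("a clean step is split within two bins of the true breakpoint", {
  bins <- fake_bins(200)
  x <- withr::with_seed(2, c(rnorm(100, 1.0, 0.05), rnorm(100, 1.5, 0.05)))
  sp <- cbs_segment(fake_ratio_profile(x), bins, seed = 3)
  expect_equal(nrow(sp$segments), 2L)
  expect_lte(abs(sp$segments$end_bin[1] - 100L), 2L)
})

test_that("a two-bin spike is isolated as its own segment", {
  bins <- fake_bins(200)
  x <- rep(1, 200)
  x[101:102] <- 4.0
  x <- x + withr::with_seed(4, rnorm(200, 0, 0.03))
  sp <- cbs_segment(fake_ratio_profile(x), bins, min_width = 2, seed = 5)
  seg <- sp$segments
  spike <- seg[seg$mean_ratio > 2, ]
  expect_equal(nrow(spike), 1L)
  expect_equal(spike$start_bin, 101L)
  expect_equal(spike$end_bin, 102L)
})

test_that("the accepted split equals the exhaustive-scan argmax", {
  ## oracle equivalence on short chromosomes with a single true change-point
  for (case in 1:12) {
    n <- withr::with_seed(100 + case, sample(10:50, 1))
    cp <- withr::with_seed(200 + case, sample(2:(n - 2), 1))
    x <- withr::with_seed(300 + case,
                          c(rnorm(cp, 1, 0.1), rnorm(n - cp, 1.6, 0.1)))
    got <- sccnv:::cpp_cbs_scan(x, 2L)
    want <- oracle_scan(x, 2)
    expect_equal(got$tmax, want$tmax, tolerance = 1e-9)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
  }
})

test_that("noiseless piecewise-constant profiles are recovered exactly", {
  bins <- fake_bins(260, chrom = c("chr1", "chr2"))
  ## chr1: 130 bins with a [41, 80] gain; chr2: flat
  x <- rep(1, 260)
  x[41:80] <- 1.5
  sp <- cbs_segment(fake_ratio_profile(x), bins, seed = 6)
  seg <- sp$segments[sp$segments$chrom == "chr1", ]
  expect_equal(seg$start_bin, c(1L, 41L, 81L))
  expect_equal(seg$end_bin, c(40L, 80L, 130L))
  expect_equal(seg$mean_ratio, c(1, 1.5, 1))
  expect_equal(nrow(sp$segments[sp$segments$chrom == "chr2", ]), 1L)
})

test_that("scaling all ratios leaves breakpoints fixed and scales means", {
  bins <- fake_bins(150)
  x <- withr::with_seed(7, c(rnorm(70, 1, 0.05), rnorm(80, 1.7, 0.05)))
  a <- cbs_segment(fake_ratio_profile(x), bins, seed = 8)
  b <- cbs_segment(fake_ratio_profile(3 * x), bins, seed = 8)
  expect_equal(a$segments$start_bin, b$segments$start_bin)
  expect_equal(b$segments$mean_ratio, 3 * a$segments$mean_ratio, tolerance = 1e-12)
})

test_that("integer copy numbers derive from the weighted-median baseline", {
  bins <- fake_bins(100)
  sp <- structure(list(cell_id = "c", segments = data.frame(
    chrom = "chr1", start_bin = c(1L, 61L, 81L), end_bin = c(60L, 80L, 100L),
    n_bins = c(60L, 20L, 20L), mean_ratio = c(1.0, 1.5, 0.5))),
    class = "segment_profile")
  cp <- call_integer_cn(sp, bins)
  expect_equal(unique(cp$cn[1:60]), 2L)
  expect_equal(unique(cp$cn[61:80]), 3L)
  expect_equal(unique(cp$cn[81:100]), 1L)
  expect_equal(nrow(cp$calls), 2L)
  ## all-diploid profile yields no calls
  flat <- structure(list(cell_id = "c", segments = data.frame(
    chrom = "chr1", start_bin = 1L, end_bin = 100L, n_bins = 100L,
    mean_ratio = 1.0)), class = "segment_profile")
  expect_equal(nrow(call_integer_cn(flat, bins)$calls), 0L)
})

test_that("calls are maximal runs with a size filter", {
  bins <- fake_bins(5, width = 30000)
  cp <- fake_cn_profile(c(2L, 2L, 3L, 3L, 2L), bins)
  calls <- extract_cnv_calls(cp)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$end - calls$start, 60000)
  expect_equal(calls$cn, 3L)
  expect_equal(nrow(extract_cnv_calls(cp, min_size_bp = 1e6)), 0L)
  diploid <- fake_cn_profile(rep(2L, 5), bins)
  expect_equal(nrow(extract_cnv_calls(diploid)), 0L)
})

test_that("degenerate chromosomes fall back to one segment with a warning", {
  bins <- fake_bins(5, chrom = c("chr1", "chr2"), width = 1000)
  ## chr1 gets 3 bins, chr2 only 2; ask for min_width 3
  expect_warning(
    sp <- cbs_segment(fake_ratio_profile(rep(1, 5)), bins, min_width = 3, seed = 1),
    "fewer bins"
  )
  expect_equal(nrow(sp$segments), 2L)
})
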