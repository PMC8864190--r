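test_that("bin-count rule follows the reads-per-bin target with clamping", {
  expect_equal(choose_bin_count(300000, 60), 5000L)
  expect_equal(choose_bin_count(300000, 30), 10000L)
  expect_equal(choose_bin_count(1000, 60), 100L) # lower clamp
  expect_equal(choose_bin_count(1e7, 30), 50000L) # upper clamp
  expect_warning(choose_bin_count(300000, 10), "recommended")
  expect_error(choose_bin_count(0, 60), "positive")
})

test_that("unweighted bins are equal width and proportional to chromosome length", {
  g <- build_genome(3, 5e7, seed = 1) # 150 Mb
  bins <- make_bins(g, 5000)
  expect_equal(nrow(bins), 5000L)
  expect_equal(median(bins$end - bins$start), 30000, tolerance = 1e-3)
  ## equal width within each chromosome (+- 1 bp from boundary rounding)
  for (ch in unique(bins$chrom)) {
    w <- bins$end[bins$chrom == ch] - bins$start[bins$chrom == ch]
    expect_lte(diff(range(w)), 1)
  }
  expect_true(all(table(bins$chrom) %in% c(1666L, 1667L, 1668L)))
  ## bins tile each chromosome exactly
  for (ch in g$chrom_names) {
    b <- bins[bins$chrom == ch, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], g$chrom_lengths[[ch]])
    expect_true(all(b$start[-1] == b$end[-nrow(b)]))
  }
  expect_true(all(bins$gc >= 0.3 & bins$gc <= 0.7))
})

test_that("a uniform weight track reproduces the unweighted boundaries", {
  g <- build_genome(3, 2e7, seed = 2)
  win <- genome_windows(g)
  b1 <- make_bins(g, 600)
  b2 <- make_bins(g, 600, weight_track = rep(1, nrow(win)) * (win$end - win$start))
  expect_equal(b1$start, b2$start)
  expect_equal(b1$end, b2$end)
})

test_that("doubling one chromosome's weight doubles its bin density", {
  g <- build_genome(4, 2e7, seed = 3)
  win <- genome_windows(g)
  w <- (win$end - win$start) * ifelse(win$chrom == "chr2", 2, 1)
  bins <- make_bins(g, 1000, weight_track = w)
  tab <- table(bins$chrom)
  per_bp <- tab / g$chrom_lengths[names(tab)]
  ratio <- per_bp[["chr2"]] / mean(per_bp[c("chr1", "chr3", "chr4")])
  expect_equal(as.numeric(ratio), 2, tolerance = 0.05)
})

test_that("read counting deduplicates by exact position", {
  bins <- fake_bins(10, width = 1000)
  rs <- fake_read_set(rep("chr1", 10), seq(100, 1000, by = 100) - 100)
  bc <- count_reads(rs, bins)
  expect_equal(sum(bc$counts), 10L)
  expect_equal(bc$dup_rate, 0)
  rs2 <- fake_read_set(rep("chr1", 10), rep(500, 10))
  bc2 <- count_reads(rs2, bins)
  expect_equal(sum(bc2$counts), 1L)
  expect_equal(bc2$umdr, 1L)
  expect_equal(bc2$dup_rate, 0.9)
})

test_that("counting is permutation-invariant and conserves reads", {
  g <- build_genome(2, 5e7, seed = 4) # large enough that chance
  bins <- make_bins(g, 100)              # position collisions are negligible
  nm <- noise_model(dup_rate = 0.2)
  rs <- simulate_cell_reads(g, clone_profile("d"), 1e5, nm, seed = 5, cell_id = "c")
  bc <- count_reads(rs, bins)
  expect_equal(bc$dup_rate, 0.2, tolerance = 0.01) # generator round-trip
  perm <- withr::with_seed(1, sample.int(length(rs$start)))
  rsp <- fake_read_set(rs$chrom[perm], rs$start[perm], cell_id = rs$cell_id)
  bcp <- count_reads(rsp, bins)
  expect_equal(bcp$counts, bc$counts)
  ## conservation: counted + dropped = unique reads
  uniq <- sum(!duplicated(paste(rs$chrom, rs$start)))
  expect_equal(sum(bc$counts) + bc$dropped, uniq)
  expect_equal(sum(bc$counts), bc$umdr)
})

test_that("GC normalization flattens pure GC bias and preserves CNV signal", {
  g <- build_genome(3, 2e7, seed = 6)
  bins <- make_bins(g, 600)
  ## flat counts -> unit ratios
  flat <- gc_normalize(fake_bin_counts(rep(200L, 600)), bins)
  expect_equal(flat$ratios, rep(1, 600), tolerance = 1e-9)
  expect_equal(mean(flat$ratios), 1, tolerance = 1e-9)
  ## linear-in-GC bias on a diploid cell is removed
  biased <- round(200 * (1 + (bins$gc - 0.5)))
  rb <- gc_normalize(fake_bin_counts(biased), bins)
  expect_lt(sd(rb$ratios), 0.02)
  ## a noiseless CN=4 bin doubles its ratio
  counts <- rep(200L, 600)
  counts[300] <- 400L
  r4 <- gc_normalize(fake_bin_counts(counts), bins)
  expect_equal(r4$ratios[300], 2.0, tolerance = 0.1)
})

test_that("GC normalization is scale invariant and rejects empty input", {
  g <- build_genome(2, 1e7, seed = 7)
  bins <- make_bins(g, 200)
  counts <- withr::with_seed(8, rpois(200, 150))
  r1 <- gc_normalize(fake_bin_counts(counts), bins)
  r5 <- gc_normalize(fake_bin_counts(counts * 5L), bins)
  expect_equal(r1$ratios, r5$ratios, tolerance = 1e-9)
  expect_error(gc_normalize(fake_bin_counts(rep(0L, 200)), bins), "degenerate")
})
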