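test_that("expected read mass is conserved and scales with copy number", {
  g <- build_genome(3, 2e7, seed = 2) # 60 Mb
  ## profile with a CN=4 region on ~2% of the genome
  p4 <- clone_profile("p4", cnv_segments("chr2", 4e6, 5.2e6, 4))
  nm <- noise_model() # no bias, Poisson, no duplicates
  w2 <- window_rates(g, clone_profile("d"), 1e6, nm)
  w4 <- window_rates(g, p4, 1e6, nm)
  expect_equal(sum(w2$mu), 1e6, tolerance = 1e-9)
  expect_equal(sum(w4$mu), 1e6, tolerance = 1e-9)
  ## realized counts: doubling CN doubles the region's reads (within 5%)
  in_region <- function(rs) sum(rs$chrom == "chr2" & rs$start >= 4e6 & rs$start < 5.2e6)
  r2 <- simulate_cell_reads(g, clone_profile("d"), 1e6, nm, seed = 3, cell_id = "a")
  r4 <- simulate_cell_reads(g, p4, 1e6, nm, seed = 4, cell_id = "b")
  expect_equal(in_region(r4) / in_region(r2), 2, tolerance = 0.05)
})

test_that("copy number zero yields no reads and bounds are respected", {
  g <- build_genome(2, 1e7, seed = 5)
  p0 <- clone_profile("del", cnv_segments("chr1", 2e6, 4e6, 0))
  rs <- simulate_cell_reads(g, p0, 2e5, noise_model(), seed = 6, cell_id = "c")
  expect_equal(sum(rs$chrom == "chr1" & rs$start >= 2e6 & rs$start < 4e6), 0L)
  expect_true(all(rs$start >= 0 & rs$start < g$chrom_lengths[rs$chrom]))
  expect_equal(rs$n_raw, length(rs$start))
})

test_that("dispersion zero gives Poisson window counts", {
  g <- build_genome(1, 5e7, gc_autocorrelation = 0, seed = 8) # 5000 windows
  rs <- simulate_cell_reads(g, clone_profile("d"), 3e5, noise_model(), seed = 9,
                            cell_id = "c")
  counts <- tabulate(rs$start %/% 1e4 + 1L, nbins = 5000L)
  ## dispersion-test oracle: variance/mean ratio of Poisson counts ~ 1
  expect_gt(var(counts) / mean(counts), 0.9)
  expect_lt(var(counts) / mean(counts), 1.1)
})

test_that("injected duplicate fraction matches the removal rate at dedup", {
  g <- build_genome(2, 2e7, seed = 10)
  nm <- noise_model(dup_rate = 0.2)
  rs <- simulate_cell_reads(g, clone_profile("d"), 1e5, nm, seed = 11, cell_id = "c")
  key <- paste(rs$chrom, rs$start)
  removed <- mean(duplicated(key))
  expect_equal(removed, 0.20, tolerance = 0.01)
})

test_that("read simulation is reproducible and profile chromosomes are checked", {
  g <- build_genome(2, 1e7, seed = 12)
  nm <- noise_model(gc_bias_strength = 2, dispersion = 0.1, dup_rate = 0.1)
  a <- simulate_cell_reads(g, clone_profile("d"), 5e4, nm, seed = 13, cell_id = "c")
  b <- simulate_cell_reads(g, clone_profile("d"), 5e4, nm, seed = 13, cell_id = "c")
  expect_identical(a, b)
  bad <- clone_profile("bad", cnv_segments("chr9", 0, 1e6, 3))
  expect_error(simulate_cell_reads(g, bad, 1e4, nm, seed = 1), "absent from genome")
})

test_that("population simulation emits one cell per requested slot", {
  g <- synthetic_genome_hg19(seed = 1)
  preset <- hcc02_preset(g)
  mix <- preset$mixtures[preset$mixtures$sample == "primary", ]
  ## count contract only: 2e3 reads per cell keeps this fast
  pop <- simulate_population(g, preset$profiles[mix$clone], mix$cells,
                            n_reads_per_cell = 2e3, noise = noise_model(),
                            seed = 20, sample_label = "primary")
  expect_length(pop$reads, 106L)
  expect_equal(nrow(pop$truth), 106L)
  expect_equal(as.integer(table(pop$truth$clone)[c("A", "B", "C", "normal")]),
               c(87L, 11L, 5L, 3L))
  empty <- simulate_population(g, preset$profiles, rep(0L, 4), 1e3,
                               noise_model(), seed = 1)
  expect_length(empty$reads, 0L)
  ## same master seed: bitwise-identical truth and read counts
  pop2 <- simulate_population(g, preset$profiles[mix$clone], mix$cells,
                             n_reads_per_cell = 2e3, noise = noise_model(),
                             seed = 20, sample_label = "primary")
  expect_identical(pop$truth, pop2$truth)
  expect_identical(vapply(pop$reads, `[[`, 0L, "n_raw"),
                   vapply(pop2$reads, `[[`, 0L, "n_raw"))
})
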