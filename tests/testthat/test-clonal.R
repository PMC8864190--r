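make_cn_set <- function(binscheme) {
  ## three nested karyotypes on 100 bins: A < B < C by event superset
  cn_A <- rep(2L, 100); cn_A[1:20] <- 3L
  cn_B <- cn_A; cn_B[31:40] <- 1L
  cn_C <- cn_B; cn_C[51:60] <- 4L
  cells <- list()
  for (i in 1:6) cells[[sprintf("a%d", i)]] <- fake_cn_profile(cn_A, binscheme, sprintf("a%d", i))
  for (i in 1:4) cells[[sprintf("b%d", i)]] <- fake_cn_profile(cn_B, binscheme, sprintf("b%d", i))
  for (i in 1:2) cells[[sprintf("c%d", i)]] <- fake_cn_profile(cn_C, binscheme, sprintf("c%d", i))
  cells
}

test_that("normal cells are the call-free, low-aberration ones", {
  bins <- fake_bins(100, width = 500000) # 50 Mb chromosome
  quiet <- fake_cn_profile(rep(2L, 100), bins, "quiet")
  loud <- fake_cn_profile(c(rep(2L, 50), rep(3L, 10), rep(2L, 40)), bins, "loud")
  ## one aberrant bin (500 kb < 3 Mb, 1% of bins): still normal
  speck_cn <- rep(2L, 100); speck_cn[7] <- 3L
  speck <- fake_cn_profile(speck_cn, bins, "speck")
  lab <- identify_normal_cells(list(quiet = quiet, loud = loud, speck = speck))
  expect_identical(lab, c(quiet = TRUE, loud = FALSE, speck = TRUE))
})

test_that("Ward clustering recovers trivial structure and ignores row order", {
  m <- rbind(c(rep(1, 50)), c(rep(1, 50)), c(rep(1.8, 50)))
  rownames(m) <- c("x", "y", "z")
  a <- cluster_clones(m, k = 2)
  lab <- setNames(a$assignment$cluster, a$assignment$cell_id)
  expect_equal(lab[["x"]], lab[["y"]])
  expect_false(lab[["x"]] == lab[["z"]])
  expect_equal(unique(cluster_clones(m, k = 1)$assignment$cluster), 1L)
  expect_error(cluster_clones(m, k = 4), "k must lie")
  ## permutation invariance of the partition
  noisy <- withr::with_seed(1, matrix(rnorm(20 * 30, rep(c(1, 1.5), times = c(8, 12))), 20, 30))
  rownames(noisy) <- sprintf("c%02d", 1:20)
  p1 <- cluster_clones(noisy, k = 2)
  perm <- withr::with_seed(2, sample.int(20))
  p2 <- cluster_clones(noisy[perm, ], k = 2)
  l1 <- setNames(p1$assignment$cluster, p1$assignment$cell_id)
  l2 <- setNames(p2$assignment$cluster, p2$assignment$cell_id)
  expect_equal(l1[names(l2)], l2)
})

test_that("consensus profiles, fractions, and descendant hints are correct", {
  bins <- fake_bins(100, width = 500000)
  cells <- make_cn_set(bins)
  asg <- fake_assignment(names(cells),
                         cluster = rep(c(1L, 2L, 3L), times = c(6, 4, 2)),
                         sample = rep(c("primary", "relapse"), times = c(8, 4)))
  cs <- clone_consensus(cells, asg)
  ## consensus of identical members equals any member
  expect_equal(unname(cs$consensus_cn["1", ]), cells$a1$cn)
  expect_equal(unname(cs$consensus_cn["3", ]), cells$c1$cn)
  ## fractions per sample sum to one
  expect_equal(unname(rowSums(cs$fractions)), c(1, 1), tolerance = 1e-9)
  ## nested karyotypes: B and C descend from A, C also from B
  h <- cs$parent_hints
  expect_true(any(h$clone == "2" & h$ancestor == "1"))
  expect_true(any(h$clone == "3" & h$ancestor == "1"))
  expect_true(any(h$clone == "3" & h$ancestor == "2"))
  expect_false(any(h$clone == "1"))
})

test_that("integer consensus resolves even-count ties toward the baseline", {
  expect_equal(sccnv:::consensus_int(c(2L, 3L)), 2L)
  expect_equal(sccnv:::consensus_int(c(3L, 4L)), 3L)
  expect_equal(sccnv:::consensus_int(c(1L, 3L)), 1L) # equidistant: lower wins
  expect_equal(sccnv:::consensus_int(c(1L, 2L, 3L)), 2L)
})

test_that("fishplot export carries parents and normalized fractions", {
  bins <- fake_bins(100, width = 500000)
  cells <- make_cn_set(bins)
  asg <- fake_assignment(names(cells),
                         cluster = rep(c(1L, 2L, 3L), times = c(6, 4, 2)),
                         sample = rep(c("primary", "relapse"), times = c(8, 4)))
  cs <- clone_consensus(cells, asg)
  fish <- export_fishplot_table(cs, c("primary", "relapse"))
  expect_equal(nrow(fish), 6L)
  sums <- tapply(fish$fraction, fish$sample, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
  ## closest ancestor (largest event set) becomes the parent
  expect_equal(unique(fish$parent[fish$clone == "3"]), "2")
  expect_equal(unique(fish$parent[fish$clone == "2"]), "1")
  expect_true(all(is.na(fish$parent[fish$clone == "1"])))
  expect_error(export_fishplot_table(cs, c("primary", "nope")), "unknown sample")
  ## single clone, single sample
  one <- clone_consensus(cells[1:3], fake_assignment(names(cells)[1:3], rep(1L, 3),
                                                     rep("primary", 3)))
  f1 <- export_fishplot_table(one, "primary")
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$fraction, 1.0)
})
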