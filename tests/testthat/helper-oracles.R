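## Independent oracles and small fixture builders shared across tests.

## Exhaustive all-(i, j) arc scan of the pooled two-sample t statistic,
## written independently of the package's segmentation code.  Arcs are
## (i, j] with both sides at least min_width bins; ties break toward the
## smallest i, then smallest j.
oracle_scan <- function(x, min_width = 2) {
  n <- length(x)
  best <- -1
  bi <- NA_integer_
  bj <- NA_integer_
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      k <- j - i
      m <- n - k
      if (m < min_width) next
      arc <- x[(i + 1):j]
      rest <- x[-((i + 1):j)]
      mA <- mean(arc)
      mB <- mean(rest)
      ssw <- sum((arc - mA)^2) + sum((rest - mB)^2)
      v <- max(ssw / max(n - 2, 1), 1e-8)
      t <- abs(mA - mB) / sqrt(v * (1 / k + 1 / m))
      if (t > best + 1e-12) {
        best <- t
        bi <- i
        bj <- j
      }
    }
  }
  list(tmax = best, i = bi, j = bj)
}

## brute-force interval overlap in bp
oracle_overlap <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

## a bare bin scheme over one or more chromosomes of equal-width bins,
## bypassing make_bins, for segmentation/QC tests that only need
## coordinates and a GC column
fake_bins <- function(n, chrom = "chr1", width = 30000, gc = NULL) {
  n_per <- rep_len(n %/% length(chrom) + (seq_along(chrom) <= n %% length(chrom)),
                   length(chrom))
  rows <- do.call(rbind, lapply(seq_along(chrom), function(ci) {
    start <- (seq_len(n_per[ci]) - 1) * width
    data.frame(chrom = chrom[ci], start = start, end = start + width,
               stringsAsFactors = FALSE)
  }))
  rows$gc <- if (is.null(gc)) rep_len(seq(0.35, 0.65, length.out = 37), nrow(rows)) else gc
  structure(rows, class = c("bin_scheme", "data.frame"), chrom_names = chrom)
}

fake_ratio_profile <- function(ratios, cell_id = "cell") {
  structure(list(cell_id = cell_id, ratios = ratios), class = "ratio_profile")
}

fake_bin_counts <- function(counts, cell_id = "cell", n_raw = sum(counts)) {
  structure(list(cell_id = cell_id, counts = counts, umdr = sum(counts),
                 n_raw = n_raw, dup_rate = 1 - sum(counts) / max(n_raw, 1),
                 dropped = 0L),
            class = "bin_counts")
}

fake_read_set <- function(chrom, start, cell_id = "cell", sample_label = "s") {
  structure(list(cell_id = cell_id, chrom = chrom, start = start,
                 n_raw = length(start), sample_label = sample_label),
            class = "read_set")
}

fake_cn_profile <- function(cn, binscheme, cell_id = "cell") {
  structure(list(cell_id = cell_id, cn = as.integer(cn),
                 calls = sccnv:::cn_runs_to_calls(as.integer(cn), binscheme)),
            class = "cn_profile")
}

fake_assignment <- function(cell_id, cluster, sample) {
  structure(list(assignment = data.frame(cell_id = cell_id, cluster = cluster,
                                         sample = sample,
                                         stringsAsFactors = FALSE),
                 tree = NULL, k = length(unique(cluster))),
            class = "clone_assignment")
}
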