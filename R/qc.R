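#' Median absolute pairwise difference of a ratio profile
#'
#' MAPD measures the evenness of coverage: the median over consecutive
#' within-chromosome bin pairs of the absolute difference of GC-normalised
#' copy ratios (genome-wide mean 1).  Pairs never straddle a chromosome
#' boundary.  Computed on linear ratios; pass `log2 = TRUE` for the log2
#' reading of the metric.
#'
#' @param ratio_profile A `ratio_profile`.
#' @param binscheme The matching `bin_scheme` (supplies chromosome bounds).
#' @param log2 Compute on `log2(ratios)` instead of linear ratios (zeros are
#'   floored at 1e-3 first).
#' @return Non-negative scalar.
#' @examples
#' # alternating 0.8 / 1.2 ratios have MAPD 0.4
#' @export
mapd <- function(ratio_profile, binscheme, log2 = FALSE) {
  r <- ratio_profile$ratios
  if (length(r) != nrow(binscheme))
    stop_invalid("ratio profile and bin scheme disagree in length")
  if (log2) r <- base::log2(pmax(r, 1e-3))
  diffs <- unlist(lapply(split(r, factor(binscheme$chrom, levels = unique(binscheme$chrom))),
                         function(x) if (length(x) > 1L) abs(diff(x)) else numeric(0)),
                  use.names = FALSE)
  if (!length(diffs))
    stop_invalid("degenerate input: fewer than 2 bins on every chromosome")
  median(diffs)
}

#' Lorenz curve of coverage uniformity
#'
#' Down-samples the cell's unique (deduplicated) reads without replacement to
#' `n_sample`, counts them in fixed-width bins across the genome, sorts the
#' bins by ascending count, and accumulates the genome fraction against the
#' read fraction.  The diagonal is perfect uniformity; the Gini coefficient
#' (1 minus twice the trapezoidal area under the curve) quantifies the
#' deviation.
#'
#' @param readset A `read_set`.
#' @param genome A `genome_model`.
#' @param bin_size Fixed bin width in bp (default 60 kb).
#' @param n_sample Number of unique reads used (default 1e5); when the cell
#'   has fewer, all are used with a warning.
#' @param seed Integer seed for the down-sampling.
#' @return A `lorenz_curve`: list with `cum_genome_fraction`,
#'   `cum_read_fraction` (both starting at 0 and ending at 1) and `gini`.
#' @export
lorenz <- function(readset, genome, bin_size = 60000, n_sample = 1e5, seed = 1) {
  validate_genome(genome)
  if (readset$n_raw == 0L || length(readset$start) == 0L)
    stop_invalid("degenerate input: empty read set")
  key <- read_keys(readset$chrom, readset$start, genome$chrom_names)
  keep <- !duplicated(key) & !is.na(key)
  chrom <- readset$chrom[keep]
  start <- readset$start[keep]
  n_unique <- length(start)
  if (n_unique < n_sample) {
    warning(sprintf("only %d unique reads available; using all of them", n_unique))
    n_sample <- n_unique
  }
  sel <- withr::with_seed(seed, sample.int(n_unique, n_sample))
  chrom <- chrom[sel]; start <- start[sel]
  ## fixed bins tiling the genome
  counts <- unlist(lapply(genome$chrom_names, function(ch) {
    nb <- ceiling(genome$chrom_lengths[[ch]] / bin_size)
    pos <- start[chrom == ch]
    tabulate(pmin(floor(pos / bin_size) + 1L, nb), nbins = nb)
  }), use.names = FALSE)
  counts <- sort(counts)
  B <- length(counts)
  gx <- seq(0, 1, length.out = B + 1L)
  ry <- c(0, cumsum(counts) / sum(counts))
  gini <- 1 - 2 * sum((ry[-1] + ry[-length(ry)]) / 2 * diff(gx))
  structure(list(cum_genome_fraction = gx, cum_read_fraction = ry, gini = gini),
            class = "lorenz_curve")
}

#' Per-cell quality summary
#'
#' Collects the quality metrics of one cell into a single row.
#'
#' @param bincounts A `bin_counts`.
#' @param ratio_profile The matching `ratio_profile`.
#' @param binscheme The matching `bin_scheme`.
#' @return One-row `data.frame`: `cell_id`, `n_raw`, `umdr`, `dup_rate`,
#'   `mapd`.
#' @export
cell_qc <- function(bincounts, ratio_profile, binscheme) {
  data.frame(
    cell_id = bincounts$cell_id,
    n_raw = bincounts$n_raw,
    umdr = bincounts$umdr,
    dup_rate = bincounts$dup_rate,
    mapd = mapd(ratio_profile, binscheme),
    stringsAsFactors = FALSE
  )
}

#' Filter cells on usable reads and MAPD
#'
#' Partition cells into pass/fail with reasons, using inclusive comparisons:
#' a cell passes when `umdr >= umdr_min` and `mapd <= mapd_max`.
#'
#' @param qc `data.frame` with at least `cell_id`, `umdr`, `mapd` (e.g. rows
#'   from [cell_qc()]).
#' @param umdr_min Minimum unique deduplicated reads (default 300000).
#' @param mapd_max Maximum MAPD (default 0.45).
#' @return List with `pass` and `fail` (subsets of `qc`, `fail` gaining a
#'   `fail_reason` column), and `summary` (counts and utilization rate
#'   `passed/total`; `NULL` utilization for empty input).
#' @export
filter_cells <- function(qc, umdr_min = 300000, mapd_max = 0.45) {
  if (nrow(qc) == 0L) {
    return(list(pass = qc, fail = cbind(qc, fail_reason = character(0)),
                summary = list(total = 0L, passed = 0L, utilization = NULL)))
  }
  ok_umdr <- qc$umdr >= umdr_min
  ok_mapd <- qc$mapd <= mapd_max
  passed <- ok_umdr & ok_mapd
  reason <- ifelse(!ok_umdr & !ok_mapd, "umdr;mapd",
                   ifelse(!ok_umdr, "umdr", ifelse(!ok_mapd, "mapd", "")))
  qc$passed <- passed
  fail <- qc[!passed, , drop = FALSE]
  fail$fail_reason <- reason[!passed]
  list(
    pass = qc[passed, , drop = FALSE],
    fail = fail,
    summary = list(total = nrow(qc), passed = sum(passed),
                   utilization = sum(passed) / nrow(qc))
  )
}
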