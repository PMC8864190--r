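#' Choose the number of bins from the usable read count
#'
#' Applies the coverage rule of 30-180 reads per bin: the bin count is the
#' usable (unique, deduplicated) read count divided by the target reads per
#' bin, rounded, and clamped to `[100, 50000]`.
#'
#' @param umdr Unique mapped deduplicated reads (> 0).
#' @param target_reads_per_bin Desired reads per bin; values outside
#'   `[30, 180]` are allowed with a warning.
#' @return Integer bin count.
#' @examples
#' choose_bin_count(300000, 60)  # 5000
#' @export
choose_bin_count <- function(umdr, target_reads_per_bin = 60) {
  if (umdr <= 0) stop_invalid("umdr must be positive")
  if (target_reads_per_bin < 30 || target_reads_per_bin > 180)
    warning("target_reads_per_bin outside the recommended [30, 180] range")
  n <- round(umdr / target_reads_per_bin)
  as.integer(min(max(n, 100), 50000))
}

#' Partition a genome into counting bins
#'
#' Without a weight track, bins have (near-)equal bp width within each
#' chromosome and the bin count per chromosome is proportional to its length
#' (largest-remainder allocation, every chromosome gets at least one bin).
#' With a weight track (e.g. an expected-read-density track), bin boundaries
#' equalise cumulative weight per bin instead, so higher-weight territory
#' receives proportionally more bins.  Each bin's GC fraction is the
#' length-weighted mean of the window GC values it covers.
#'
#' @param genome A `genome_model`.
#' @param n_bins Total number of bins (at least one per chromosome).
#' @param weight_track Optional non-negative weight per GC window, in the row
#'   order of [genome_windows()].
#' @return A `bin_scheme`: `data.frame` with columns `chrom`, `start`, `end`,
#'   `gc` (0-based half-open, sorted), carrying the genome's chromosome order
#'   as attribute `chrom_names`.
#' @export
make_bins <- function(genome, n_bins, weight_track = NULL) {
  validate_genome(genome)
  n_chrom <- length(genome$chrom_names)
  if (n_bins < n_chrom) stop_invalid("n_bins must be at least the number of chromosomes")
  win <- genome_windows(genome)
  if (n_bins > nrow(win)) stop_invalid("n_bins exceeds the number of GC windows")
  wlen <- win$end - win$start
  w <- if (is.null(weight_track)) wlen else {
    if (length(weight_track) != nrow(win))
      stop_invalid("weight_track must have one value per GC window (%d)", nrow(win))
    if (any(weight_track < 0)) stop_invalid("weights must be non-negative")
    weight_track
  }
  ## largest-remainder allocation of bins to chromosomes, min 1 each
  wtot <- tapply(w, factor(win$chrom, levels = genome$chrom_names), sum)
  share <- n_bins * wtot / sum(wtot)
  nb <- pmax(floor(share), 1)
  rem <- n_bins - sum(nb)
  if (rem > 0) {
    o <- order(share - floor(share), decreasing = TRUE)
    nb[o[seq_len(rem)]] <- nb[o[seq_len(rem)]] + 1
  } else if (rem < 0) {
    o <- order(share - floor(share))
    take <- o[nb[o] > 1][seq_len(-rem)]
    nb[take] <- nb[take] - 1
  }
  out <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    ch <- genome$chrom_names[ci]
    sel <- win$chrom == ch
    wend <- win$end[sel]
    cw <- cumsum(w[sel])
    cgc <- cumsum(win$gc[sel] * wlen[sel])
    targets <- seq(0, cw[length(cw)], length.out = nb[ci] + 1)
    bnd <- approx(c(0, cw), c(0, wend), xout = targets, ties = "ordered")$y
    bnd <- round(bnd)
    bnd[1] <- 0
    bnd[length(bnd)] <- genome$chrom_lengths[[ch]]
    bnd <- cummax(bnd)
    if (any(diff(bnd) <= 0))
      stop_invalid("degenerate bin boundaries on %s (weights too concentrated)", ch)
    gmass <- approx(c(0, wend), c(0, cgc), xout = bnd, ties = "ordered")$y
    out[[ci]] <- data.frame(
      chrom = ch, start = bnd[-length(bnd)], end = bnd[-1],
      gc = diff(gmass) / diff(bnd), stringsAsFactors = FALSE
    )
  }
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  structure(bins, class = c("bin_scheme", "data.frame"),
            chrom_names = genome$chrom_names)
}

bin_ids <- function(bins) sprintf("%s:%d-%d", bins$chrom, bins$start, bins$end)

## unique-read key: exact (chrom, start) within a cell
read_keys <- function(chrom, start, chrom_names) {
  match(chrom, chrom_names) * 2^40 + start
}

#' Count reads per bin with positional deduplication
#'
#' Reads with an identical (chrom, start) within the cell beyond the first
#' are treated as PCR duplicates and removed (when `dedup = TRUE`).  Each
#' retained read is assigned to the bin containing its start; reads on
#' unknown chromosomes or outside any bin are dropped and counted.
#'
#' @param readset A `read_set`.
#' @param binscheme A `bin_scheme` from [make_bins()].
#' @param dedup Remove positional duplicates before counting (default TRUE).
#' @return A `bin_counts`: list with `cell_id`, `counts` (integer per bin),
#'   `umdr` (unique deduplicated reads counted), `n_raw`, `dup_rate`
#'   (`1 - umdr / n_raw`), `dropped`.
#' @export
count_reads <- function(readset, binscheme, dedup = TRUE) {
  chrom_names <- attr(binscheme, "chrom_names") %||% unique(binscheme$chrom)
  chrom <- readset$chrom
  start <- readset$start
  key <- read_keys(chrom, start, chrom_names)
  known <- !is.na(key)
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    message(sprintf("count_reads: skipped %d reads on unknown chromosomes", n_unknown))
  chrom <- chrom[known]; start <- start[known]; key <- key[known]
  if (dedup) {
    keep <- !duplicated(key)
    chrom <- chrom[keep]; start <- start[keep]
  }
  umdr <- length(start)
  counts <- integer(nrow(binscheme))
  dropped <- n_unknown
  offset <- 0L
  for (ch in chrom_names) {
    bsel <- which(binscheme$chrom == ch)
    rsel <- chrom == ch
    if (length(bsel) && any(rsel)) {
      pos <- start[rsel]
      idx <- findInterval(pos, binscheme$start[bsel])
      inside <- idx >= 1L & pos < binscheme$end[bsel][pmax(idx, 1L)]
      dropped <- dropped + sum(!inside)
      tb <- tabulate(idx[inside], nbins = length(bsel))
      counts[bsel] <- tb
    } else if (any(rsel)) {
      dropped <- dropped + sum(rsel)
    }
    offset <- offset + length(bsel)
  }
  if (dropped > n_unknown)
    message(sprintf("count_reads: dropped %d reads outside bins", dropped - n_unknown))
  structure(list(cell_id = readset$cell_id, counts = counts,
                 umdr = umdr - (dropped - n_unknown),
                 n_raw = readset$n_raw,
                 dup_rate = 1 - umdr / max(readset$n_raw, 1L),
                 dropped = dropped),
            class = "bin_counts")
}

#' GC-normalise bin counts into copy ratios
#'
#' Fits a robust locally weighted regression (lowess, 3 robustifying
#' iterations) of count against bin GC fraction, divides each count by the
#' fitted value (floored at `1e-6 * mean(count)`), and rescales so the
#' genome-wide mean ratio is exactly 1.  At copy number 2 the expected ratio
#' is 1.  When more than 30% of bins deviate more than two-fold from the fit,
#' a note is emitted: heavy aneuploidy can distort a plain GC fit.
#'
#' @param bincounts A `bin_counts` (at least 1000 usable reads recommended).
#' @param binscheme The matching `bin_scheme` (at least 50 bins).
#' @param span Lowess span as a fraction of points (default 0.3).
#' @return A `ratio_profile`: list with `cell_id` and `ratios` (non-negative,
#'   mean exactly 1).
#' @export
gc_normalize <- function(bincounts, binscheme, span = 0.3) {
  counts <- as.numeric(bincounts$counts)
  if (length(counts) != nrow(binscheme))
    stop_invalid("bin counts and bin scheme disagree in length")
  if (length(counts) < 50) stop_invalid("need at least 50 bins for GC normalization")
  if (all(counts == 0)) stop_invalid("degenerate input: all bin counts are zero")
  if (sum(counts) < 1000)
    warning("fewer than 1000 usable reads; GC fit will be unstable")
  lx <- lowess(binscheme$gc, counts, f = span, iter = 3)
  fit <- approx(lx$x, lx$y, xout = binscheme$gc, rule = 2, ties = "ordered")$y
  eps <- 1e-6 * mean(counts)
  ratios <- counts / pmax(fit, eps)
  frac_dev <- mean(ratios > 2 | ratios < 0.5)
  if (frac_dev > 0.30)
    message(sprintf(
      "gc_normalize: %.0f%% of bins deviate >2-fold from the GC fit; profile may be heavily aneuploid",
      100 * frac_dev))
  ratios <- ratios / mean(ratios)
  structure(list(cell_id = bincounts$cell_id, ratios = ratios),
            class = "ratio_profile")
}
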