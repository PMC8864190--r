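## recursive CBS on one chromosome: returns sorted 0-based internal
## breakpoints (a breakpoint b splits bins 1..b | b+1..n)
cbs_breaks <- function(x, alpha, nperm, min_width) {
  n <- length(x)
  if (n < 2L * min_width) return(integer(0))
  sc <- cpp_cbs_scan(x, min_width)
  if (sc$i < 0L) return(integer(0))
  p <- cpp_cbs_perm_p(x, sc$tmax, min_width, nperm, alpha,
                      if (nperm > 200L) 100L else nperm)
  if (p >= alpha) return(integer(0))
  br <- c(if (sc$i > 0L) sc$i, if (sc$j < n) sc$j)
  bounds <- c(0L, br, n)
  kids <- integer(0)
  for (s in seq_len(length(bounds) - 1L)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    if (b - a >= 2L * min_width)
      kids <- c(kids, a + cbs_breaks(x[(a + 1L):b], alpha, nperm, min_width))
  }
  sort(unique(c(br, kids)))
}

## merge adjacent segments whose mean difference is below `th`, smallest
## difference first; seg is a data.frame with n_bins and mean_ratio
undo_merge <- function(seg, th) {
  if (th <= 0) return(seg)
  repeat {
    if (nrow(seg) < 2L) return(seg)
    d <- abs(diff(seg$mean_ratio))
    i <- which.min(d)
    if (d[i] >= th) return(seg)
    w <- seg$n_bins[c(i, i + 1L)]
    seg$mean_ratio[i] <- sum(seg$mean_ratio[c(i, i + 1L)] * w) / sum(w)
    seg$n_bins[i] <- sum(w)
    seg$end_bin[i] <- seg$end_bin[i + 1L]
    seg <- seg[-(i + 1L), , drop = FALSE]
  }
}

#' Segment a ratio profile by circular binary segmentation
#'
#' Per chromosome, recursively finds the arc of bins maximising the pooled
#' two-sample t-statistic between in-arc and out-of-arc bins and accepts the
#' split when its permutation p-value (full within-chromosome shuffles of the
#' bins, same statistic) is below `alpha`; recursion continues on the
#' resulting pieces.  Afterwards, adjacent segments whose mean difference is
#' below `undo_sd` times the MAD of bin-to-bin ratio differences are merged
#' back.  The statistic operates on untransformed ratios.  Deterministic
#' given `seed`.
#'
#' @param ratio_profile A `ratio_profile` from [gc_normalize()].
#' @param binscheme The matching `bin_scheme`.
#' @param alpha Split acceptance level of the permutation test.
#' @param nperm Number of permutations per tested split.
#' @param min_width Minimum segment width in bins.
#' @param undo_sd Merge threshold in MAD units of bin-to-bin differences;
#'   0 disables merging.
#' @param seed Integer seed for the permutation shuffles.
#' @return A `segment_profile`: list with `cell_id` and `segments`
#'   (`data.frame`: `chrom`, `start_bin`, `end_bin` (global 1-based,
#'   inclusive), `n_bins`, `mean_ratio`); segments partition the bins of each
#'   chromosome.
#' @export
cbs_segment <- function(ratio_profile, binscheme, alpha = 0.01, nperm = 1000,
                        min_width = 2, undo_sd = 1.0, seed = 1) {
  r <- ratio_profile$ratios
  if (length(r) != nrow(binscheme))
    stop_invalid("ratio profile and bin scheme disagree in length")
  chrom_names <- attr(binscheme, "chrom_names") %||% unique(binscheme$chrom)
  seg_list <- list()
  diffs <- numeric(0)
  withr::with_seed(seed, {
    for (ch in chrom_names) {
      idx <- which(binscheme$chrom == ch)
      if (!length(idx)) next
      x <- r[idx]
      if (length(x) > 1L) diffs <- c(diffs, diff(x))
      if (length(x) < min_width) {
        warning(sprintf("chromosome %s has fewer bins than min_width; returned as one segment", ch))
        br <- integer(0)
      } else {
        br <- cbs_breaks(x, alpha, nperm, min_width)
      }
      bounds <- c(0L, br, length(x))
      for (s in seq_len(length(bounds) - 1L)) {
        a <- bounds[s]; b <- bounds[s + 1L]
        seg_list[[length(seg_list) + 1L]] <- data.frame(
          chrom = ch,
          start_bin = idx[1L] + a,
          end_bin = idx[1L] + b - 1L,
          n_bins = b - a,
          mean_ratio = mean(x[(a + 1L):b]),
          stringsAsFactors = FALSE
        )
      }
    }
  })
  seg <- do.call(rbind, seg_list)
  th <- if (length(diffs) > 0L) undo_sd * mad(diffs) else 0
  if (!is.finite(th)) th <- 0
  merged <- lapply(split(seg, factor(seg$chrom, levels = chrom_names)),
                   undo_merge, th = th)
  seg <- do.call(rbind, merged)
  rownames(seg) <- NULL
  structure(list(cell_id = ratio_profile$cell_id, segments = seg),
            class = "segment_profile")
}

#' Assign integer copy numbers to segments
#'
#' The per-cell diploid baseline is the bin-count-weighted median of segment
#' mean ratios; each segment's copy number is
#' `round(assumed_ploidy * mean_ratio / baseline)` clipped to `[0, max_cn]`.
#' Discrete CNV calls are the maximal runs of constant copy number different
#' from `assumed_ploidy`, converted to bp through the bin boundaries; calls
#' never span chromosomes.  A warning is emitted when less than 30% of the
#' genome sits at the baseline, where a fixed-ploidy scaling may be wrong.
#'
#' @param segment_profile A `segment_profile`.
#' @param binscheme The matching `bin_scheme`.
#' @param assumed_ploidy Baseline integer ploidy (default 2).
#' @param max_cn Largest callable copy number (default 12).
#' @return A `cn_profile`: list with `cell_id`, `cn` (integer per bin),
#'   `calls` (`data.frame`: `chrom`, `start`, `end`, `cn` in bp coordinates).
#' @export
call_integer_cn <- function(segment_profile, binscheme, assumed_ploidy = 2,
                            max_cn = 12) {
  seg <- segment_profile$segments
  if (is.null(seg) || nrow(seg) == 0L) stop_invalid("segment profile is empty")
  baseline <- weighted_median(seg$mean_ratio, seg$n_bins)
  if (baseline <= 0) stop_invalid("degenerate input: baseline segment ratio is zero")
  cn_seg <- pmin(pmax(floor(assumed_ploidy * seg$mean_ratio / baseline + 0.5), 0), max_cn)
  cn <- integer(nrow(binscheme))
  for (i in seq_len(nrow(seg)))
    cn[seg$start_bin[i]:seg$end_bin[i]] <- cn_seg[i]
  if (mean(cn == assumed_ploidy) < 0.30)
    warning("less than 30% of the genome at baseline ploidy; fixed-ploidy scaling may be unreliable")
  calls <- cn_runs_to_calls(cn, binscheme, baseline_cn = assumed_ploidy)
  structure(list(cell_id = segment_profile$cell_id, cn = as.integer(cn),
                 calls = calls),
            class = "cn_profile")
}

## maximal runs of constant cn != baseline within chromosomes, in bp
cn_runs_to_calls <- function(cn, binscheme, baseline_cn = 2) {
  grp <- run_ids(paste(binscheme$chrom, cn))
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  calls <- data.frame(
    chrom = binscheme$chrom[first],
    start = binscheme$start[first],
    end = binscheme$end[last],
    cn = cn[first],
    stringsAsFactors = FALSE
  )
  calls <- calls[calls$cn != baseline_cn, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Extract discrete CNV calls above a size threshold
#'
#' @param cn_profile A `cn_profile`.
#' @param min_size_bp Minimum call size in bp (default 0: all calls).
#' @return `data.frame` of calls (`chrom`, `start`, `end`, `cn`).
#' @export
extract_cnv_calls <- function(cn_profile, min_size_bp = 0) {
  calls <- cn_profile$calls
  calls[calls$end - calls$start >= min_size_bp, , drop = FALSE]
}
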