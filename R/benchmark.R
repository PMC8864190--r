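#' Run the per-cell calling chain on one read set
#'
#' Convenience wrapper: count reads into bins, GC-normalise, segment by CBS,
#' and assign integer copy numbers.
#'
#' @param readset A `read_set`.
#' @param binscheme A `bin_scheme`.
#' @param alpha,nperm,min_width,undo_sd,seed Passed to [cbs_segment()].
#' @param span Passed to [gc_normalize()].
#' @return List with `counts`, `ratios`, `segments`, `cn`.
#' @export
call_cell <- function(readset, binscheme, alpha = 0.01, nperm = 1000,
                      min_width = 2, undo_sd = 1.0, span = 0.3, seed = 1) {
  bc <- count_reads(readset, binscheme)
  rp <- gc_normalize(bc, binscheme, span = span)
  sp <- cbs_segment(rp, binscheme, alpha = alpha, nperm = nperm,
                    min_width = min_width, undo_sd = undo_sd, seed = seed)
  cp <- call_integer_cn(sp, binscheme)
  list(counts = bc, ratios = rp, segments = sp, cn = cp)
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Match detected CNV calls against simulated truth
#'
#' A detected call can validate a truth segment of the same direction
#' (gain/loss relative to `baseline_cn`) when their overlap is at least
#' `min_overlap` of the reference length (`mode = "truth"`: the truth
#' segment's length; `"detected"`: the call's length; `"reciprocal"`: both).
#' Candidate pairs are assigned greedily by descending overlap, each truth
#' segment validating at most one call.  Unvalidated calls are false
#' positives; unmatched truth segments are false negatives.  At
#' `min_overlap = 0`, any nonempty overlap qualifies.
#'
#' @param detected,truth `data.frame`s of segments (`chrom`, `start`, `end`,
#'   `cn`) in bp on the same genome; truth segments must not overlap.
#' @param min_overlap Required overlap fraction (default 0.5).
#' @param mode Which length the fraction refers to.
#' @param baseline_cn Copy number regarded as normal (default 2).
#' @return A `match_result`: list with `tp`, `fp`, `fn` and `matched_pairs`
#'   (`data.frame` of detected/truth row indices and overlap bp).
#' @export
match_cnvs <- function(detected, truth, min_overlap = 0.5,
                       mode = c("truth", "detected", "reciprocal"),
                       baseline_cn = 2) {
  mode <- match.arg(mode)
  validate_segments(truth)
  n_det <- nrow(detected)
  n_tru <- nrow(truth)
  cand <- NULL
  if (n_det > 0L && n_tru > 0L) {
    rows <- list()
    for (d in seq_len(n_det)) {
      same <- which(truth$chrom == detected$chrom[d] &
                      sign(truth$cn - baseline_cn) == sign(detected$cn[d] - baseline_cn))
      if (!length(same)) next
      ov <- overlap_len(detected$start[d], detected$end[d],
                        truth$start[same], truth$end[same])
      need <- switch(mode,
        truth = min_overlap * (truth$end[same] - truth$start[same]),
        detected = rep(min_overlap * (detected$end[d] - detected$start[d]), length(same)),
        reciprocal = pmax(min_overlap * (truth$end[same] - truth$start[same]),
                          min_overlap * (detected$end[d] - detected$start[d]))
      )
      ok <- ov > 0 & ov >= need
      if (any(ok))
        rows[[length(rows) + 1L]] <- data.frame(detected = d, truth = same[ok],
                                                overlap = ov[ok])
    }
    if (length(rows)) cand <- do.call(rbind, rows)
  }
  pairs <- data.frame(detected = integer(0), truth = integer(0), overlap = numeric(0))
  if (!is.null(cand)) {
    cand <- cand[order(-cand$overlap, cand$truth, cand$detected), , drop = FALSE]
    used_d <- logical(n_det)
    used_t <- logical(n_tru)
    for (i in seq_len(nrow(cand))) {
      d <- cand$detected[i]; t <- cand$truth[i]
      if (!used_d[d] && !used_t[t]) {
        used_d[d] <- TRUE; used_t[t] <- TRUE
        pairs <- rbind(pairs, cand[i, , drop = FALSE])
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = n_det - tp, fn = n_tru - tp,
                 matched_pairs = pairs),
            class = "match_result")
}

#' Sensitivity and false discovery rate of a match result
#'
#' `sensitivity = TP / (TP + FN)` and `fdr = FP / (FP + TP)`; a metric whose
#' denominator is zero is reported as `NA`.
#'
#' @param match A `match_result` from [match_cnvs()].
#' @return List with `sensitivity` and `fdr`.
#' @export
accuracy_metrics <- function(match) {
  sens <- if (match$tp + match$fn > 0) match$tp / (match$tp + match$fn) else NA_real_
  fdr <- if (match$tp + match$fp > 0) match$fp / (match$fp + match$tp) else NA_real_
  list(sensitivity = sens, fdr = fdr)
}

#' Sensitivity/FDR sweep over CNV size and bin count
#'
#' For each combination of CNV size, replicate, and bin count: spike `count`
#' non-overlapping CNVs of that size into the genome, simulate one cell with
#' `umdr` unique deduplicated reads under `noise`, run the full calling chain
#' (bin, GC-normalise, segment, integer CN), match the calls against the
#' spiked truth at >= 50% truth overlap, and record TP/FP/FN with the derived
#' sensitivity and FDR.
#'
#' @param genome A `genome_model` large enough to hold `count` segments of
#'   the largest size without covering half the genome.
#' @param sizes_mb CNV sizes in Mb.
#' @param count Spiked CNVs per replicate.
#' @param replicates Replicates per size.
#' @param n_bins_options Bin counts to evaluate.
#' @param umdr Unique deduplicated reads per simulated cell.
#' @param noise A `noise_model`.
#' @param seed Master seed; all sub-seeds derive from it.
#' @param min_overlap,mode Matching rule, see [match_cnvs()].
#' @param alpha,nperm,min_width,undo_sd Segmentation parameters.
#' @return `data.frame` with one row per (size, replicate, bins):
#'   `size_mb`, `replicate`, `n_bins`, `tp`, `fp`, `fn`, `sensitivity`,
#'   `fdr`.
#' @export
run_size_sweep <- function(genome, sizes_mb = c(1, 2, 3, 5, 10, 15),
                           count = 20, replicates = 5,
                           n_bins_options = c(5000, 10000, 20000),
                           umdr = 300000, noise = default_noise_model(),
                           seed = 1, min_overlap = 0.5, mode = "truth",
                           alpha = 0.01, nperm = 1000, min_width = 2,
                           undo_sd = 1.0) {
  schemes <- lapply(n_bins_options, function(nb) make_bins(genome, nb))
  names(schemes) <- as.character(n_bins_options)
  n_raw <- round(umdr / (1 - noise$dup_rate))
  rows <- list()
  for (size in sizes_mb) {
    for (rep_i in seq_len(replicates)) {
      for (nb in n_bins_options) {
        s <- derive_seed(seed, "sweep", size, rep_i, nb)
        truth_profile <- spike_random_cnvs(genome, size * 1e6, count,
                                           seed = derive_seed(s, "spike"))
        cell <- simulate_cell_reads(genome, truth_profile, n_raw, noise,
                                    seed = derive_seed(s, "reads"),
                                    cell_id = sprintf("sw_%g_%d_%d", size, rep_i, nb))
        res <- call_cell(cell, schemes[[as.character(nb)]], alpha = alpha,
                         nperm = nperm, min_width = min_width,
                         undo_sd = undo_sd, seed = derive_seed(s, "cbs"))
        m <- match_cnvs(extract_cnv_calls(res$cn), truth_profile$segments,
                        min_overlap = min_overlap, mode = mode)
        am <- accuracy_metrics(m)
        rows[[length(rows) + 1L]] <- data.frame(
          size_mb = size, replicate = rep_i, n_bins = nb,
          tp = m$tp, fp = m$fp, fn = m$fn,
          sensitivity = am$sensitivity, fdr = am$fdr
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median sensitivity and FDR per (size, bins) of a sweep
#'
#' @param sweep Output of [run_size_sweep()].
#' @return `data.frame`: `size_mb`, `n_bins`, `median_sensitivity`,
#'   `median_fdr` (medians over replicates, `NA` rows dropped per metric).
#' @export
sweep_summary <- function(sweep) {
  key <- interaction(sweep$size_mb, sweep$n_bins, drop = TRUE)
  rows <- lapply(split(sweep, key), function(d) data.frame(
    size_mb = d$size_mb[1], n_bins = d$n_bins[1],
    median_sensitivity = median(d$sensitivity, na.rm = TRUE),
    median_fdr = median(d$fdr, na.rm = TRUE)
  ))
  out <- do.call(rbind, rows)
  out <- out[order(out$size_mb, out$n_bins), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default down-sampling schedule for saturation analysis
#'
#' @return Increasing vector of unique-read depths from 3e4 to 2e6.
#' @export
saturation_schedule <- function() {
  c(3e4, 6e4, 9e4, 1.2e5, 1.5e5, 1.8e5, 2.1e5, 2.4e5, 2.7e5, 3e5,
    4.5e5, 6.5e5, 1.05e6, 1.5e6, 2e6)
}

#' Sequencing-saturation analysis of one cell
#'
#' Calls per-bin integer copy number at each down-sampled depth (sampling
#' unique reads without replacement) and at full depth; the fraction of
#' full-depth copy-number-abnormal bins recovered at each depth is smoothed
#' by locally weighted regression over log-depth (and made monotone by a
#' running maximum).  The saturation point is the smallest scheduled depth
#' whose smoothed fraction reaches `plateau_frac` of the full-depth value.
#'
#' @param readset A `read_set` (its unique reads must cover the schedule;
#'   otherwise the schedule is truncated with a warning).
#' @param genome A `genome_model`.
#' @param schedule Increasing vector of unique-read depths.
#' @param n_bins Number of bins for calling.
#' @param seed Master seed (per-depth sampling seeds derive from it).
#' @param plateau_frac Plateau threshold (default 0.99).
#' @param alpha,nperm,min_width,undo_sd,span Calling parameters.
#' @return A `saturation_curve`: list with `depths`, `detected_fraction`
#'   (raw), `smoothed_fraction`, `saturation_point`, `n_abnormal_bins`; or a
#'   null curve (with a warning) when the cell has no abnormal bins at full
#'   depth.
#' @export
saturation_analysis <- function(readset, genome, schedule = saturation_schedule(),
                                n_bins = 5000, seed = 1, plateau_frac = 0.99,
                                alpha = 0.01, nperm = 1000, min_width = 2,
                                undo_sd = 1.0, span = 0.3) {
  validate_genome(genome)
  if (is.unsorted(schedule, strictly = TRUE))
    stop_invalid("schedule depths must be strictly increasing")
  binscheme <- make_bins(genome, n_bins)
  key <- read_keys(readset$chrom, readset$start, genome$chrom_names)
  keep <- !duplicated(key) & !is.na(key)
  chrom <- readset$chrom[keep]
  start <- readset$start[keep]
  n_unique <- length(start)
  if (n_unique < max(schedule)) {
    warning(sprintf("only %d unique reads; truncating schedule", n_unique))
    schedule <- schedule[schedule <= n_unique]
    if (!length(schedule)) stop_invalid("no schedule depth is reachable")
  }
  call_at <- function(idx, sub_seed) {
    rs <- structure(list(cell_id = readset$cell_id, chrom = chrom[idx],
                         start = start[idx], n_raw = length(idx),
                         sample_label = readset$sample_label),
                    class = "read_set")
    call_cell(rs, binscheme, alpha = alpha, nperm = nperm,
              min_width = min_width, undo_sd = undo_sd, span = span,
              seed = sub_seed)$cn$cn
  }
  cn_full <- call_at(seq_len(n_unique), derive_seed(seed, "full"))
  abn_full <- which(cn_full != 2L)
  if (!length(abn_full)) {
    warning("no abnormal bins at full depth; saturation curve is undefined")
    return(structure(list(depths = schedule,
                          detected_fraction = rep(NA_real_, length(schedule)),
                          smoothed_fraction = rep(NA_real_, length(schedule)),
                          saturation_point = NA_real_, n_abnormal_bins = 0L),
                     class = "saturation_curve"))
  }
  frac <- vapply(seq_along(schedule), function(i) {
    d <- schedule[i]
    cn_d <- if (d == n_unique) cn_full else {
      idx <- withr::with_seed(derive_seed(seed, "depth", d),
                              sample.int(n_unique, d))
      call_at(idx, derive_seed(seed, "call", d))
    }
    length(intersect(which(cn_d != 2L), abn_full)) / length(abn_full)
  }, numeric(1))
  lx <- log10(schedule)
  ## degree-2 loess needs a comfortable number of depths; short schedules
  ## fall back to a linear local fit, and a failed fit to the raw fractions
  deg <- if (length(schedule) >= 7) 2 else 1
  spn <- if (length(schedule) >= 7) 0.75 else 1
  sm <- tryCatch(
    suppressWarnings(predict(loess(frac ~ lx, span = spn, degree = deg))),
    error = function(e) frac
  )
  sm <- cummax(pmin(pmax(sm, 0), 1))
  target <- plateau_frac * sm[length(sm)]
  sat <- schedule[which(sm >= target)[1L]]
  structure(list(depths = schedule, detected_fraction = frac,
                 smoothed_fraction = sm, saturation_point = sat,
                 n_abnormal_bins = length(abn_full)),
            class = "saturation_curve")
}
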