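#' Identify normal (copy-number-quiet) cells
#'
#' A cell is designated normal when it carries no CNV call of at least
#' `min_call_size` bp and its fraction of copy-number-abnormal bins does not
#' exceed `max_abnormal_fraction`.
#'
#' @param cn_profiles Named list of `cn_profile`s.
#' @param min_call_size Smallest call (bp) that marks a cell as tumor.
#' @param max_abnormal_fraction Tolerated abnormal-bin fraction.
#' @param baseline_cn Normal copy number (default 2).
#' @return Named logical vector (`TRUE` = normal).
#' @export
identify_normal_cells <- function(cn_profiles, min_call_size = 3e6,
                                  max_abnormal_fraction = 0.02,
                                  baseline_cn = 2) {
  vapply(cn_profiles, function(cp) {
    big <- cp$calls$end - cp$calls$start >= min_call_size
    !any(big) && mean(cp$cn != baseline_cn) <= max_abnormal_fraction
  }, logical(1))
}

#' Expand segment profiles into a cells x bins ratio matrix
#'
#' Each cell's row carries its segment mean ratio replicated over the bins of
#' the segment — the smoothed "segment ratio" representation used for
#' clustering.
#'
#' @param segment_profiles Named list of `segment_profile`s.
#' @param binscheme The common `bin_scheme`.
#' @return Numeric matrix, one row per cell (rownames = cell ids), one
#'   column per bin.
#' @export
segment_ratio_matrix <- function(segment_profiles, binscheme) {
  n_bins <- nrow(binscheme)
  m <- matrix(NA_real_, nrow = length(segment_profiles), ncol = n_bins,
              dimnames = list(vapply(segment_profiles, `[[`, "", "cell_id"), NULL))
  for (i in seq_along(segment_profiles)) {
    seg <- segment_profiles[[i]]$segments
    for (s in seq_len(nrow(seg)))
      m[i, seg$start_bin[s]:seg$end_bin[s]] <- seg$mean_ratio[s]
  }
  if (anyNA(m)) stop_invalid("segment profiles do not cover all bins")
  m
}

#' Indices of bins on selected chromosomes
#'
#' @param binscheme A `bin_scheme`.
#' @param chroms Chromosome names.
#' @return Integer vector of bin indices.
#' @export
bins_on_chroms <- function(binscheme, chroms) which(binscheme$chrom %in% chroms)

#' Cluster cells into clones from segment ratios
#'
#' Ward clustering (`hclust` method `ward.D2`) of Euclidean distances between
#' per-bin segment ratios, optionally restricted to a subset of bins (e.g.
#' the chromosomes carrying clone-discriminating events).  The tree is cut at
#' `k` clusters and cluster labels are renumbered by decreasing size.
#'
#' @param ratio_matrix Cells x bins matrix from [segment_ratio_matrix()].
#' @param k Number of clusters (1 <= k <= number of cells).
#' @param restrict_bins Optional bin (column) indices to cluster on.
#' @param sample_labels Optional named vector or vector aligned with rows,
#'   recording each cell's sample of origin.
#' @return A `clone_assignment`: list with `assignment` (`data.frame`:
#'   `cell_id`, `cluster`, `sample`), `tree` (the `hclust` object), `k`.
#' @export
cluster_clones <- function(ratio_matrix, k, restrict_bins = NULL,
                           sample_labels = NULL) {
  n <- nrow(ratio_matrix)
  if (k < 1 || k > n) stop_invalid("k must lie in [1, number of cells]")
  m <- if (is.null(restrict_bins)) ratio_matrix else
    ratio_matrix[, restrict_bins, drop = FALSE]
  hc <- hclust(dist(m), method = "ward.D2")
  cl <- cutree(hc, k = k)
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- as.integer(relabel[as.character(cl)])
  smp <- if (is.null(sample_labels)) rep(NA_character_, n) else {
    if (!is.null(names(sample_labels)))
      as.character(sample_labels[rownames(ratio_matrix)])
    else as.character(rep_len(sample_labels, n))
  }
  structure(list(
    assignment = data.frame(cell_id = rownames(ratio_matrix), cluster = cl,
                            sample = smp, stringsAsFactors = FALSE),
    tree = hc, k = k
  ), class = "clone_assignment")
}

consensus_int <- function(v, center = 2L) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2L == 1L) return(s[(n + 1L) %/% 2L])
  lo <- s[n %/% 2L]; hi <- s[n %/% 2L + 1L]
  if (lo == hi) return(lo)
  ## even-count tie: take the middle value closest to the baseline
  if (abs(lo - center) <= abs(hi - center)) lo else hi
}

#' Consensus clone profiles and per-sample clone fractions
#'
#' The consensus copy number of a clone at each bin is the per-clone median
#' (even-count ties resolved toward the value closest to the baseline).
#' Per-sample clone fractions are computed over the assigned (tumor) cells.
#' Clone X is flagged a descendant candidate of clone Y when X's abnormal
#' bins form a strict superset of Y's with at least 95% agreement on Y's
#' events.
#'
#' @param cn_profiles Named list of `cn_profile`s covering every assigned
#'   cell.
#' @param assignment A `clone_assignment` from [cluster_clones()].
#' @param baseline_cn Normal copy number (default 2).
#' @param superset_agreement Required agreement on the ancestor's event bins.
#' @return A `clone_summary`: list with `consensus_cn` (clones x bins
#'   matrix), `counts` and `fractions` (samples x clones), `parent_hints`
#'   (`data.frame`: `clone`, `ancestor`).
#' @export
clone_consensus <- function(cn_profiles, assignment, baseline_cn = 2,
                            superset_agreement = 0.95) {
  a <- assignment$assignment
  missing <- setdiff(a$cell_id, names(cn_profiles))
  if (length(missing))
    stop_invalid("no CN profile for cells: %s", paste(missing, collapse = ", "))
  clones <- sort(unique(a$cluster))
  n_bins <- length(cn_profiles[[a$cell_id[1]]]$cn)
  cons <- matrix(NA_integer_, nrow = length(clones), ncol = n_bins,
                 dimnames = list(as.character(clones), NULL))
  for (ci in seq_along(clones)) {
    cells <- a$cell_id[a$cluster == clones[ci]]
    if (!length(cells)) { warning("empty clone excluded"); next }
    cnm <- vapply(cells, function(cid) cn_profiles[[cid]]$cn, integer(n_bins))
    cons[ci, ] <- apply(matrix(cnm, nrow = n_bins), 1, consensus_int,
                        center = baseline_cn)
  }
  counts <- table(sample = a$sample, clone = factor(a$cluster, levels = clones))
  fractions <- sweep(counts, 1, pmax(rowSums(counts), 1L), "/")
  ## descendant hints by the strict-superset rule on abnormal bins
  hints <- list()
  for (x in seq_along(clones)) for (y in seq_along(clones)) {
    if (x == y) next
    ev_x <- which(cons[x, ] != baseline_cn)
    ev_y <- which(cons[y, ] != baseline_cn)
    if (!length(ev_y) || length(ev_x) <= length(ev_y)) next
    agree <- mean(cons[x, ev_y] == cons[y, ev_y])
    if (agree >= superset_agreement && all(ev_y %in% ev_x))
      hints[[length(hints) + 1L]] <- data.frame(
        clone = as.character(clones[x]), ancestor = as.character(clones[y]),
        stringsAsFactors = FALSE)
  }
  ## a normal-like clone (no events) is an ancestor of every event-carrying clone
  for (x in seq_along(clones)) for (y in seq_along(clones)) {
    if (x == y) next
    if (!any(cons[y, ] != baseline_cn) && any(cons[x, ] != baseline_cn))
      hints[[length(hints) + 1L]] <- data.frame(
        clone = as.character(clones[x]), ancestor = as.character(clones[y]),
        stringsAsFactors = FALSE)
  }
  hints <- if (length(hints)) unique(do.call(rbind, hints)) else
    data.frame(clone = character(0), ancestor = character(0))
  structure(list(consensus_cn = cons, counts = counts, fractions = fractions,
                 parent_hints = hints, baseline_cn = baseline_cn),
            class = "clone_summary")
}

#' Export per-sample clone fractions for fishplot-style rendering
#'
#' One row per (sample, clone) with the clone's cell fraction in that sample
#' and its inferred parent (the ancestor candidate with the largest event
#' set, or `NA` for a founding clone).  Fractions within a sample sum to 1.
#'
#' @param clone_summary A `clone_summary`.
#' @param sample_order Samples to export, in display order.
#' @return `data.frame`: `sample`, `clone`, `fraction`, `parent`.
#' @export
export_fishplot_table <- function(clone_summary, sample_order) {
  fr <- clone_summary$fractions
  unknown <- setdiff(sample_order, rownames(fr))
  if (length(unknown))
    stop_invalid("unknown sample(s): %s", paste(unknown, collapse = ", "))
  cons <- clone_summary$consensus_cn
  n_events <- rowSums(cons != clone_summary$baseline_cn)
  parent_of <- function(cl) {
    anc <- clone_summary$parent_hints$ancestor[clone_summary$parent_hints$clone == cl]
    if (!length(anc)) return(NA_character_)
    anc[which.max(n_events[anc])]
  }
  rows <- list()
  for (smp in sample_order) for (cl in colnames(fr)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = smp, clone = cl, fraction = as.numeric(fr[smp, cl]),
      parent = parent_of(cl), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
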