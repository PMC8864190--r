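## All genomic files written by this package use 0-based half-open
## coordinates (BED convention).  1-based input is not auto-detected.

write_tsv_with_header <- function(df, path, header_lines = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_comments <- function(path, ...) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, ...)
}

#' Write read sets as a sorted BED file
#'
#' Columns: `chrom`, `start`, `end` (= start + `read_len`), `cell_id`;
#' 0-based half-open, sorted by cell, chromosome, start.
#'
#' @param readsets List of `read_set`s.
#' @param path Output path.
#' @param read_len Read length used for the `end` column (default 100).
#' @param chrom_order Chromosome sort order (default order of appearance).
#' @return The path, invisibly.
#' @export
write_reads_bed <- function(readsets, path, read_len = 100, chrom_order = NULL) {
  if (inherits(readsets, "read_set")) readsets <- list(readsets)
  rows <- lapply(readsets, function(rs) data.frame(
    chrom = rs$chrom, start = rs$start, end = rs$start + read_len,
    cell_id = rs$cell_id, stringsAsFactors = FALSE))
  bed <- do.call(rbind, rows)
  if (is.null(chrom_order)) chrom_order <- unique(bed$chrom)
  bed <- bed[order(bed$cell_id, match(bed$chrom, chrom_order), bed$start), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-cell read positions from a BED file
#'
#' Expects the 4-column layout of [write_reads_bed()] (no header).  Malformed
#' lines are reported with their line numbers.
#'
#' @param path BED path.
#' @param genome Optional `genome_model`; when given, coordinates are
#'   validated against chromosome bounds.
#' @return Named list of `read_set`s (one per cell id).
#' @export
read_reads_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 4L)
  if (length(bad))
    stop_invalid("malformed BED line(s): %s", paste(utils::head(bad, 5), collapse = ", "))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- as.numeric(vapply(parts, `[[`, "", 2L))
  cell <- vapply(parts, `[[`, "", 4L)
  if (anyNA(start)) stop_invalid("non-numeric start coordinate in %s", path)
  if (!is.null(genome)) {
    bad <- is.na(match(chrom, genome$chrom_names)) |
      start < 0 | start >= genome$chrom_lengths[chrom]
    if (any(bad))
      stop_invalid("read outside chromosome bounds at line %d (%s:%d)",
                   which(bad)[1], chrom[which(bad)[1]], start[which(bad)[1]])
  }
  out <- lapply(split(seq_along(cell), cell), function(idx) {
    structure(list(cell_id = cell[idx[1]], chrom = chrom[idx],
                   start = start[idx], n_raw = length(idx),
                   sample_label = NA_character_),
              class = "read_set")
  })
  out[unique(cell)]
}

#' Write clone profiles as a SEG-like TSV
#'
#' Columns: `clone`, `chrom`, `start`, `end`, `cn` (0-based half-open).
#'
#' @param profiles List of `clone_profile`s.
#' @param path Output path.
#' @param header_lines Optional comment lines (written prefixed with `#`).
#' @return The path, invisibly.
#' @export
write_profiles_seg <- function(profiles, path, header_lines = NULL) {
  if (inherits(profiles, "clone_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (nrow(p$segments) == 0L) return(NULL)
    cbind(clone = p$name, p$segments)
  })
  seg <- do.call(rbind, rows)
  if (is.null(seg))
    seg <- data.frame(clone = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), cn = integer(0))
  write_tsv_with_header(seg, path, header_lines)
}

#' Read clone profiles from a SEG-like TSV
#'
#' Validates the per-clone non-overlap invariant.
#'
#' @param path Input path (layout of [write_profiles_seg()]).
#' @return Named list of `clone_profile`s.
#' @export
read_profiles_seg <- function(path) {
  seg <- read_tsv_skip_comments(path)
  need <- c("clone", "chrom", "start", "end", "cn")
  if (!all(need %in% names(seg)))
    stop_invalid("unknown column layout; expected %s", paste(need, collapse = ", "))
  out <- lapply(split(seg, seg$clone), function(d)
    clone_profile(d$clone[1], cnv_segments(d$chrom, d$start, d$end, d$cn)))
  out[unique(seg$clone)]
}

#' Write segment/CN profiles as a SEG-style TSV
#'
#' Columns: `cell_id`, `chrom`, `start`, `end`, `n_bins`, `mean_ratio`, `cn`
#' (bp coordinates from the bin scheme; `cn` is `NA` when no CN profile is
#' supplied for the cell).
#'
#' @param segment_profiles Named list of `segment_profile`s.
#' @param binscheme The matching `bin_scheme`.
#' @param cn_profiles Optional named list of `cn_profile`s.
#' @param path Output path.
#' @param header_lines Optional comment lines.
#' @return The path, invisibly.
#' @export
write_segments_seg <- function(segment_profiles, binscheme, path,
                               cn_profiles = NULL, header_lines = NULL) {
  rows <- lapply(segment_profiles, function(sp) {
    seg <- sp$segments
    cn <- if (!is.null(cn_profiles) && sp$cell_id %in% names(cn_profiles)) {
      cnv <- cn_profiles[[sp$cell_id]]$cn
      vapply(seq_len(nrow(seg)), function(i) cnv[seg$start_bin[i]], 0L)
    } else rep(NA_integer_, nrow(seg))
    data.frame(cell_id = sp$cell_id, chrom = seg$chrom,
               start = binscheme$start[seg$start_bin],
               end = binscheme$end[seg$end_bin],
               n_bins = seg$n_bins, mean_ratio = seg$mean_ratio, cn = cn,
               stringsAsFactors = FALSE)
  })
  write_tsv_with_header(do.call(rbind, rows), path, header_lines)
}

#' Write a cells x bins matrix as TSV
#'
#' Header row holds bin ids `chrom:start-end`; first column `cell_id`.
#'
#' @param mat Numeric matrix, rownames = cell ids.
#' @param binscheme The matching `bin_scheme` (supplies bin ids).
#' @param path Output path.
#' @param header_lines Optional comment lines.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(mat, binscheme, path, header_lines = NULL) {
  df <- data.frame(cell_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("cell_id", bin_ids(binscheme))
  write_tsv_with_header(df, path, header_lines)
}

#' Read a cells x bins matrix from TSV
#'
#' @param path Input path (layout of [write_matrix_tsv()]).
#' @return Numeric matrix with cell ids as rownames and bin ids as colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_skip_comments(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a bin scheme as BED + GC TSV
#'
#' @param binscheme A `bin_scheme`.
#' @param path Output path.
#' @param header_lines Optional comment lines.
#' @return The path, invisibly.
#' @export
write_bins_tsv <- function(binscheme, path, header_lines = NULL) {
  write_tsv_with_header(as.data.frame(binscheme), path, header_lines)
}

#' Write a Lorenz curve as a two-column TSV
#'
#' Columns: `cum_genome_fraction`, `cum_read_fraction`, plus the Gini
#' coefficient in a header comment.
#'
#' @param lorenz_curve A `lorenz_curve` from [lorenz()].
#' @param path Output path.
#' @param header_lines Optional extra comment lines.
#' @return The path, invisibly.
#' @export
write_lorenz_tsv <- function(lorenz_curve, path, header_lines = NULL) {
  df <- data.frame(cum_genome_fraction = lorenz_curve$cum_genome_fraction,
                   cum_read_fraction = lorenz_curve$cum_read_fraction)
  write_tsv_with_header(df, path,
                        c(header_lines, sprintf("gini=%.6f", lorenz_curve$gini)))
}

#' Write a clustering merge history as a TSV
#'
#' One row per internal node of the dendrogram: `node`, `left`, `right`,
#' `height`.  Negative child values are leaf (cell) indices, positive values
#' earlier nodes, following [hclust()]'s merge convention; leaf labels are
#' appended as comment lines.
#'
#' @param assignment A `clone_assignment` whose `tree` is an `hclust`.
#' @param path Output path.
#' @param header_lines Optional comment lines.
#' @return The path, invisibly.
#' @export
write_linkage_tsv <- function(assignment, path, header_lines = NULL) {
  hc <- assignment$tree
  if (is.null(hc)) stop_invalid("assignment carries no linkage tree")
  df <- data.frame(node = seq_len(nrow(hc$merge)),
                   left = hc$merge[, 1], right = hc$merge[, 2],
                   height = hc$height)
  write_tsv_with_header(df, path,
                        c(header_lines,
                          paste("leaves:", paste(hc$labels, collapse = ","))))
}
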