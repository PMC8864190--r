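#' Construct a table of copy-number segments
#'
#' Segments use 0-based half-open bp coordinates and integer copy numbers in
#' `[0, 12]`.
#'
#' @param chrom Chromosome identifiers.
#' @param start,end Segment bounds in bp (0-based, half-open; `start < end`).
#' @param cn Non-negative integer copy numbers (at most 12).
#' @return A validated `data.frame` with columns `chrom`, `start`, `end`, `cn`.
#' @export
cnv_segments <- function(chrom = character(), start = numeric(),
                         end = numeric(), cn = integer()) {
  seg <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), cn = as.integer(cn),
                    stringsAsFactors = FALSE)
  validate_segments(seg)
  seg
}

validate_segments <- function(seg, allow_overlap = FALSE) {
  if (nrow(seg) == 0L) return(invisible(seg))
  if (any(seg$start >= seg$end)) stop_invalid("segments must satisfy start < end")
  if (any(seg$cn < 0 | seg$cn > 12)) stop_invalid("copy numbers must lie in [0, 12]")
  if (!allow_overlap) {
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
        stop_invalid("segments overlap on %s", ch)
    }
  }
  invisible(seg)
}

#' Define a clone karyotype
#'
#' A clone profile is a set of non-overlapping copy-number segments on top of
#' a uniform baseline (diploid by default): any region not covered by a
#' segment has copy number `baseline_cn`.
#'
#' @param name Clone label.
#' @param segments A segment table from [cnv_segments()] (may be empty for a
#'   normal karyotype).
#' @param baseline_cn Baseline integer copy number (default 2).
#' @return A `clone_profile` object.
#' @export
clone_profile <- function(name, segments = cnv_segments(), baseline_cn = 2L) {
  validate_segments(segments)
  structure(list(name = name, segments = segments,
                 baseline_cn = as.integer(baseline_cn)),
            class = "clone_profile")
}

#' @export
print.clone_profile <- function(x, ...) {
  cat(sprintf("clone_profile '%s': %d segments, baseline CN %d\n",
              x$name, nrow(x$segments), x$baseline_cn))
  invisible(x)
}

check_profile_on_genome <- function(profile, genome) {
  seg <- profile$segments
  if (nrow(seg) == 0L) return(invisible(TRUE))
  bad <- !(seg$chrom %in% genome$chrom_names)
  if (any(bad))
    stop_invalid("profile references chromosomes absent from genome: %s",
                 paste(unique(seg$chrom[bad]), collapse = ", "))
  if (any(seg$end > genome$chrom_lengths[seg$chrom]))
    stop_invalid("profile segments extend beyond chromosome ends")
  invisible(TRUE)
}

#' Spike random fixed-size CNVs into a genome
#'
#' Places exactly `count` non-overlapping segments of exactly `size_bp` bp,
#' with copy numbers drawn from `cn_choices`.  Placement is uniform over
#' valid positions (chromosomes weighted by the number of admissible start
#' positions) and deterministic given `seed`.
#'
#' @param genome A `genome_model`.
#' @param size_bp Segment size in bp (at least one GC window).
#' @param count Number of segments; `count * size_bp` must be below half the
#'   genome length.
#' @param seed Integer seed.
#' @param cn_choices Integer copy numbers to sample from (default gain 3 /
#'   loss 1).
#' @param max_tries Bounded number of rejection-sampling attempts before a
#'   placement failure is raised.
#' @return A `clone_profile` named `"spike"` carrying the placed segments.
#' @export
spike_random_cnvs <- function(genome, size_bp, count, seed = 1,
                              cn_choices = c(1L, 3L), max_tries = 200 * max(count, 1)) {
  validate_genome(genome)
  if (count < 0) stop_invalid("count must be non-negative")
  if (size_bp < genome$window_bp) stop_invalid("size_bp must be at least one GC window")
  if (count * size_bp >= 0.5 * genome$total_length)
    stop_invalid("requested CNVs would cover half the genome or more")
  if (count == 0L) return(clone_profile("spike"))
  lens <- genome$chrom_lengths
  slots <- pmax(lens - size_bp + 1, 0)
  if (all(slots == 0)) stop_invalid("no chromosome can hold a segment of %d bp", size_bp)
  placed <- vector("list", count)
  withr::with_seed(seed, {
    n_ok <- 0L
    tries <- 0L
    while (n_ok < count) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("placement-failure: could not place non-overlapping CNVs after bounded retries",
             call. = FALSE)
      ch <- sample(genome$chrom_names, 1L, prob = slots)
      start <- floor(runif(1) * slots[[ch]])
      end <- start + size_bp
      overlap <- FALSE
      if (n_ok > 0L) {
        for (p in placed[seq_len(n_ok)]) {
          if (p$chrom == ch && start < p$end && p$start < end) { overlap <- TRUE; break }
        }
      }
      if (overlap) next
      n_ok <- n_ok + 1L
      placed[[n_ok]] <- list(chrom = ch, start = start, end = end,
                             cn = sample(as.integer(cn_choices), 1L))
    }
  })
  seg <- do.call(rbind, lapply(placed, as.data.frame, stringsAsFactors = FALSE))
  seg <- seg[order(match(seg$chrom, genome$chrom_names), seg$start), , drop = FALSE]
  rownames(seg) <- NULL
  clone_profile("spike", cnv_segments(seg$chrom, seg$start, seg$end, seg$cn))
}
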