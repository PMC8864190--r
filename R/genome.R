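## hg19 autosome lengths (bp), used by synthetic_genome_hg19() to give the
## synthetic reference realistic relative chromosome sizes.
HG19_CHROM_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566
)

new_genome_model <- function(chrom_names, chrom_lengths, window_bp, gc) {
  names(chrom_lengths) <- chrom_names
  names(gc) <- chrom_names
  g <- structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = chrom_lengths,
      window_bp = window_bp,
      gc = gc,
      total_length = sum(chrom_lengths)
    ),
    class = "genome_model"
  )
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  stopifnot(inherits(g, "genome_model"))
  if (g$total_length <= 0) stop_invalid("genome total length must be positive")
  for (ch in g$chrom_names) {
    n_expect <- ceiling(g$chrom_lengths[[ch]] / g$window_bp)
    if (length(g$gc[[ch]]) != n_expect)
      stop_invalid("GC track of %s does not tile the chromosome", ch)
    if (any(g$gc[[ch]] < 0 | g$gc[[ch]] > 1))
      stop_invalid("GC fractions must lie in [0, 1]")
  }
  invisible(g)
}

## bounded smooth random walk around 0.5, clipped to [0.30, 0.70].
## rho = 0 gives mutually independent window values.
gc_random_walk <- function(n, rho, gc_sd) {
  if (rho < 0 || rho >= 1) stop_invalid("gc_autocorrelation must lie in [0, 1)")
  innov_sd <- gc_sd * sqrt(1 - rho^2)
  z1 <- rnorm(1, 0, gc_sd)
  if (n == 1L) {
    z <- z1
  } else {
    eps <- rnorm(n - 1L, 0, innov_sd)
    z <- c(z1, stats::filter(eps, rho, method = "recursive", init = z1))
  }
  pmin(pmax(0.5 + as.numeric(z), 0.30), 0.70)
}

#' Build a synthetic reference genome with a GC track
#'
#' Creates a `genome_model`: a set of chromosomes plus a per-window GC-fraction
#' track.  The GC track is a bounded smooth random walk (an AR(1) process
#' around 0.5, clipped to `[0.30, 0.70]`); `gc_autocorrelation = 0` yields
#' independent window values.
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param chrom_length_bp Chromosome length(s) in bp; a scalar (all equal) or
#'   a vector of length `n_chroms`.  Each must be at least 1 Mb.
#' @param gc_autocorrelation Lag-1 autocorrelation of the GC walk, in `[0, 1)`.
#' @param window_bp GC-track window width in bp (default 10 kb).  Windows tile
#'   each chromosome; the last window may be short.
#' @param gc_sd Stationary standard deviation of the GC walk before clipping.
#' @param seed Integer seed; the genome is fully determined by its arguments.
#' @param chrom_names Optional chromosome identifiers (default `chr1`, ...).
#' @return A `genome_model` with fields `chrom_names`, `chrom_lengths`,
#'   `window_bp`, `gc` (list of per-window GC fractions per chromosome), and
#'   `total_length`.
#' @examples
#' g <- build_genome(3, 5e7, seed = 1)
#' g$total_length
#' @export
build_genome <- function(n_chroms, chrom_length_bp, gc_autocorrelation = 0.9,
                         window_bp = 1e4, gc_sd = 0.05, seed = 1,
                         chrom_names = NULL) {
  if (n_chroms < 1) stop_invalid("n_chroms must be >= 1")
  lens <- rep_len(as.numeric(chrom_length_bp), n_chroms)
  if (any(lens < 1e6)) stop_invalid("chromosome lengths must be at least 1 Mb")
  if (window_bp <= 0) stop_invalid("window_bp must be positive")
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chroms))
  gc <- withr::with_seed(seed, {
    lapply(lens, function(L) gc_random_walk(ceiling(L / window_bp),
                                            gc_autocorrelation, gc_sd))
  })
  new_genome_model(chrom_names, lens, window_bp, gc)
}

#' Synthetic genome with hg19-proportioned autosomes
#'
#' A 22-chromosome `genome_model` whose chromosome lengths are the hg19
#' autosome lengths multiplied by `scale`.  The default `scale = 0.05` (1/20)
#' gives a ~144 Mb genome on which 5000-bin analyses and >= 1 Mb (scaled)
#' copy-number events stay meaningful at desk scale; `scale = 1` reproduces
#' full hg19 proportions for benchmarks that need genuinely megabase-sized
#' events.
#'
#' @param scale Multiplier applied to the hg19 autosome lengths.
#' @inheritParams build_genome
#' @return A `genome_model`.
#' @export
synthetic_genome_hg19 <- function(scale = 0.05, gc_autocorrelation = 0.9,
                                  window_bp = 1e4, gc_sd = 0.05, seed = 1) {
  lens <- round(HG19_CHROM_LENGTHS * scale)
  build_genome(length(lens), lens, gc_autocorrelation, window_bp, gc_sd, seed,
               chrom_names = names(lens))
}

#' Window table of a genome model
#'
#' Expands the per-window GC track into a data frame of half-open windows.
#'
#' @param genome A `genome_model`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `gc`
#'   (0-based half-open coordinates).
#' @export
genome_windows <- function(genome) {
  validate_genome(genome)
  out <- lapply(genome$chrom_names, function(ch) {
    L <- genome$chrom_lengths[[ch]]
    n <- length(genome$gc[[ch]])
    start <- (seq_len(n) - 1) * genome$window_bp
    data.frame(
      chrom = ch, start = start,
      end = pmin(start + genome$window_bp, L),
      gc = genome$gc[[ch]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "genome_model: %d chromosomes, %.1f Mb total, %d-bp GC windows\n",
    length(x$chrom_names), x$total_length / 1e6, as.integer(x$window_bp)
  ))
  invisible(x)
}
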