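## Karyotype anchors for the liver-tumor clonal scenario, expressed in hg19
## bp on the autosome each event lives on.  When the preset is applied to a
## scaled synthetic genome, each anchor is mapped proportionally onto the
## corresponding chromosome (fraction of hg19 length -> fraction of the
## synthetic chromosome).  `NA` end = chromosome end.
##
## Shared events (all tumor clones): gains on chr5 (whole), chr6p, chr7
## (whole), chr8q, chr15q; losses on chr6q and chr8p.
## Minor-clone events (clones B and C only): chr1q gain, chr10q loss,
## chr14q loss.  Clone C additionally amplifies distal chr1q to CN 4,
## modelling further progression of the relapse-dominant clone.
.HCC02_SHARED <- data.frame(
  chrom = c("chr5", "chr6", "chr6", "chr7", "chr8", "chr8", "chr15"),
  start = c(0, 0, 65.0e6, 0, 0, 45.6e6, 22.7e6),
  end   = c(NA, 65.0e6, NA, NA, 43.1e6, NA, NA),
  cn    = c(3L, 3L, 1L, 3L, 1L, 3L, 3L),
  stringsAsFactors = FALSE
)
.HCC02_MINOR <- data.frame(
  chrom = c("chr1", "chr10", "chr14"),
  start = c(142.6e6, 42.3e6, 100.4e6),
  end   = c(NA, 92.3e6, NA),
  cn    = c(3L, 1L, 1L),
  stringsAsFactors = FALSE
)
## distal boundary (hg19 bp) where clone C's chr1q gain steps from CN 3 to 4
.HCC02_C_SPLIT <- 190e6

map_hg19_interval <- function(genome, chrom, start_bp, end_bp) {
  idx <- match(chrom, names(HG19_CHROM_LENGTHS))
  L_ref <- HG19_CHROM_LENGTHS[[idx]]
  ch <- genome$chrom_names[[idx]]
  L <- genome$chrom_lengths[[idx]]
  if (is.na(end_bp)) end_bp <- L_ref
  c(start = round(start_bp / L_ref * L), end = round(end_bp / L_ref * L))
}

map_event_table <- function(genome, tab) {
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    iv <- map_hg19_interval(genome, tab$chrom[i], tab$start[i], tab$end[i])
    idx <- match(tab$chrom[i], names(HG19_CHROM_LENGTHS))
    data.frame(chrom = genome$chrom_names[[idx]], start = iv[["start"]],
               end = iv[["end"]], cn = tab$cn[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Three-clone paired-sample tumor scenario
#'
#' Builds the clone karyotypes and sample mixtures of a hepatocellular-
#' carcinoma-like scenario with a primary and a relapse sample.  Clone A (the
#' primary-dominant clone) carries shared chromosome-arm gains (5, 6p, 7, 8q,
#' 15q) and losses (6q, 8p).  Clones B and C additionally carry the
#' minor-clone events: a 1q gain, a 10q loss, and a distal 14q loss; clone C
#' further amplifies distal 1q (CN 4), modelling the progressed state that
#' dominates the relapse.  A `normal` profile with no segments represents
#' diploid stromal cells.
#'
#' Default mixtures: primary sample = 87 clone-A + 11 clone-B + 5 clone-C
#' tumor cells (16 minor-clone cells, 15.5% of 103 tumor cells) + 3 normal
#' cells; relapse sample = 12 clone-B + 102 clone-C tumor cells + 4 normal
#' cells.
#'
#' @param genome A `genome_model` with at least 15 chromosomes, onto which
#'   the event coordinates are mapped proportionally.
#' @return A list with `profiles` (named list of `clone_profile`s: `A`, `B`,
#'   `C`, `normal`), `mixtures` (data.frame `sample`, `clone`, `cells`), and
#'   `minor_chroms` (chromosome names carrying the minor-clone events, used
#'   to restrict the clonal clustering).
#' @export
hcc02_preset <- function(genome) {
  validate_genome(genome)
  if (length(genome$chrom_names) < 15)
    stop_invalid("genome must have at least 15 chromosomes to place all events")
  shared <- map_event_table(genome, .HCC02_SHARED)
  minor <- map_event_table(genome, .HCC02_MINOR)
  ## clone C: split the 1q gain at the progression boundary, distal part CN 4
  split_at <- map_hg19_interval(genome, "chr1", .HCC02_C_SPLIT, NA)[["start"]]
  m1 <- minor[minor$chrom == minor$chrom[1], , drop = FALSE][1, ]
  minor_c <- rbind(
    data.frame(chrom = m1$chrom, start = m1$start, end = split_at, cn = 3L,
               stringsAsFactors = FALSE),
    data.frame(chrom = m1$chrom, start = split_at, end = m1$end, cn = 4L,
               stringsAsFactors = FALSE),
    minor[-1, , drop = FALSE]
  )
  mk <- function(name, tab) {
    tab <- tab[order(match(tab$chrom, genome$chrom_names), tab$start), , drop = FALSE]
    clone_profile(name, cnv_segments(tab$chrom, tab$start, tab$end, tab$cn))
  }
  profiles <- list(
    A = mk("A", shared),
    B = mk("B", rbind(shared, minor)),
    C = mk("C", rbind(shared, minor_c)),
    normal = clone_profile("normal")
  )
  for (p in profiles) check_profile_on_genome(p, genome)
  mixtures <- data.frame(
    sample = c(rep("primary", 4L), rep("relapse", 4L)),
    clone = rep(c("A", "B", "C", "normal"), 2L),
    cells = c(87L, 11L, 5L, 3L, 0L, 12L, 102L, 4L),
    stringsAsFactors = FALSE
  )
  idx <- match(.HCC02_MINOR$chrom, names(HG19_CHROM_LENGTHS))
  list(profiles = profiles, mixtures = mixtures,
       minor_chroms = genome$chrom_names[idx])
}
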