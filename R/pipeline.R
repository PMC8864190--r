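#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end run with validated defaults.
#' The defaults reproduce the package's paired-sample clonal scenario at
#' desk scale.
#'
#' @param genome_scale Scale of the hg19-proportioned synthetic genome.
#' @param gc_autocorrelation GC-walk autocorrelation.
#' @param window_bp GC window width (bp).
#' @param noise A `noise_model`.
#' @param n_reads_per_cell Raw reads simulated per cell.
#' @param n_bins Bin count; `NULL` to derive it per cell via
#'   [choose_bin_count()] from `target_reads_per_bin`.
#' @param target_reads_per_bin Target coverage per bin when `n_bins` is NULL.
#' @param alpha,nperm,min_width,undo_sd Segmentation parameters.
#' @param span GC-normalisation lowess span.
#' @param umdr_min,mapd_max QC thresholds.
#' @param k Number of clones for clustering.
#' @param restrict_to_minor_chroms Cluster on the minor-clone chromosomes
#'   only (as the clonal analysis does) instead of the whole genome.
#' @param mixtures Optional mixture table overriding the preset's
#'   (`data.frame`: `sample`, `clone`, `cells`).
#' @param seed Master seed recorded in every output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome_scale = 0.05, gc_autocorrelation = 0.9,
                            window_bp = 1e4, noise = default_noise_model(),
                            n_reads_per_cell = 333334, n_bins = 5000,
                            target_reads_per_bin = 60,
                            alpha = 0.01, nperm = 1000, min_width = 2,
                            undo_sd = 1.0, span = 0.3,
                            umdr_min = 300000, mapd_max = 0.45,
                            k = 3, restrict_to_minor_chroms = TRUE,
                            mixtures = NULL, seed = 1) {
  stopifnot(genome_scale > 0, n_reads_per_cell >= 1, umdr_min >= 0,
            mapd_max >= 0, k >= 1)
  structure(list(
    genome_scale = genome_scale, gc_autocorrelation = gc_autocorrelation,
    window_bp = window_bp, noise = unclass(noise)[c("gc_bias_strength", "dispersion", "dup_rate")],
    n_reads_per_cell = n_reads_per_cell, n_bins = n_bins,
    target_reads_per_bin = target_reads_per_bin,
    alpha = alpha, nperm = nperm, min_width = min_width, undo_sd = undo_sd,
    span = span, umdr_min = umdr_min, mapd_max = mapd_max, k = k,
    restrict_to_minor_chroms = restrict_to_minor_chroms,
    mixtures = mixtures, seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  noise <- if (!is.null(y$noise))
    noise_model(y$noise$gc_bias_strength %||% 0, y$noise$dispersion %||% 0,
                y$noise$dup_rate %||% 0)
  else default_noise_model()
  mix <- if (!is.null(y$mixtures)) as.data.frame(do.call(rbind, lapply(
    y$mixtures, function(r) data.frame(sample = r$sample, clone = r$clone,
                                       cells = as.integer(r$cells)))))
  y$noise <- NULL
  y$mixtures <- NULL
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, c(args, list(noise = noise, mixtures = mix)))
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$mixtures))
    y$mixtures <- lapply(seq_len(nrow(y$mixtures)), function(i)
      as.list(y$mixtures[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end simulate-and-call pipeline
#'
#' Simulates the paired-sample clonal scenario under the configuration,
#' counts and GC-normalises every cell, applies the QC filter, segments and
#' calls integer copy number for the passing cells, separates normal cells,
#' clusters the tumor cells into `k` clones, builds consensus clone profiles,
#' and exports a fishplot-ready clone-fraction table.  Every output file
#' records the master seed and a configuration hash in its header; rerunning
#' with the same configuration reproduces identical files.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the manifest `data.frame` (`file`, `stage`, `md5`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  hash <- config_hash(config)
  hdr <- c(sprintf("seed=%d", seed), sprintf("config_hash=%s", hash))
  manifest <- data.frame(file = character(0), stage = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  logf <- file.path(outdir, "run_log.txt")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon))
  logmsg <- function(...) writeLines(sprintf(...), logcon)
  logmsg("sccnv %s", as.character(packageVersion("sccnv")))
  logmsg("seed=%d config_hash=%s", seed, hash)
  add <- function(path, stage) {
    manifest <<- rbind(manifest, data.frame(
      file = basename(path), stage = stage,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE))
    logmsg("[%s] wrote %s", stage, basename(path))
  }
  cfg_path <- file.path(outdir, "config.yaml")
  write_config_yaml(config, cfg_path)
  add(cfg_path, "config")

  ## simulate
  genome <- synthetic_genome_hg19(scale = config$genome_scale,
                                  gc_autocorrelation = config$gc_autocorrelation,
                                  window_bp = config$window_bp,
                                  seed = derive_seed(seed, "genome"))
  preset <- hcc02_preset(genome)
  if (!is.null(config$mixtures)) preset$mixtures <- config$mixtures
  noise <- noise_model(config$noise$gc_bias_strength, config$noise$dispersion,
                       config$noise$dup_rate)
  sim <- simulate_hcc02(genome, preset, config$n_reads_per_cell, noise,
                        seed = derive_seed(seed, "simulate"))
  truth_path <- file.path(outdir, "truth.tsv")
  write_tsv_with_header(sim$truth, truth_path, hdr)
  add(truth_path, "simulate")

  ## bin + normalise + QC
  n_bins <- config$n_bins %||%
    choose_bin_count(round(config$n_reads_per_cell * (1 - noise$dup_rate)),
                     config$target_reads_per_bin)
  bins <- make_bins(genome, n_bins)
  counts <- lapply(sim$reads, count_reads, binscheme = bins)
  ratios <- lapply(counts, gc_normalize, binscheme = bins, span = config$span)
  qc <- do.call(rbind, lapply(names(counts), function(cid)
    cell_qc(counts[[cid]], ratios[[cid]], bins)))
  flt <- filter_cells(qc, umdr_min = config$umdr_min, mapd_max = config$mapd_max)
  qc_out <- qc
  qc_out$passed <- qc$cell_id %in% flt$pass$cell_id
  reasons <- stats::setNames(rep("", nrow(qc)), qc$cell_id)
  if (nrow(flt$fail)) reasons[flt$fail$cell_id] <- flt$fail$fail_reason
  qc_out$fail_reason <- unname(reasons)
  qc_path <- file.path(outdir, "qc.tsv")
  write_tsv_with_header(qc_out, qc_path, hdr)
  add(qc_path, "qc")
  logmsg("QC: %d/%d cells passed (utilization %.3f)", flt$summary$passed,
         flt$summary$total, flt$summary$utilization %||% NA_real_)
  if (flt$summary$passed == 0L) {
    manifest_path <- file.path(outdir, "manifest.tsv")
    write_tsv_with_header(manifest, manifest_path, hdr)
    message("run_pipeline: all cells failed QC; pipeline stopped after the QC stage")
    return(invisible(manifest))
  }
  keep <- flt$pass$cell_id

  ## segment + call
  segs <- lapply(keep, function(cid)
    cbs_segment(ratios[[cid]], bins, alpha = config$alpha, nperm = config$nperm,
                min_width = config$min_width, undo_sd = config$undo_sd,
                seed = derive_seed(seed, "cbs", cid)))
  names(segs) <- keep
  cns <- lapply(segs, call_integer_cn, binscheme = bins)
  seg_path <- file.path(outdir, "segments.seg.tsv")
  write_segments_seg(segs, bins, seg_path, cn_profiles = cns, header_lines = hdr)
  add(seg_path, "segment")

  ## normal cells, clustering, consensus
  normal <- identify_normal_cells(cns)
  tumor <- keep[!normal[keep]]
  sample_of <- stats::setNames(sim$truth$sample, sim$truth$cell_id)
  rm_mat <- segment_ratio_matrix(segs[tumor], bins)
  restrict <- if (isTRUE(config$restrict_to_minor_chroms))
    bins_on_chroms(bins, preset$minor_chroms) else NULL
  k_use <- min(config$k, length(tumor))
  asg <- cluster_clones(rm_mat, k = k_use, restrict_bins = restrict,
                        sample_labels = sample_of)
  asg_out <- asg$assignment
  asg_out$normal <- FALSE
  if (any(normal[keep])) {
    asg_out <- rbind(asg_out, data.frame(
      cell_id = keep[normal[keep]], cluster = NA_integer_,
      sample = unname(sample_of[keep[normal[keep]]]), normal = TRUE))
  }
  asg_path <- file.path(outdir, "assignment.tsv")
  write_tsv_with_header(asg_out, asg_path, hdr)
  add(asg_path, "clone")
  cs <- clone_consensus(cns, asg)
  fish <- export_fishplot_table(cs, unique(preset$mixtures$sample))
  fish_path <- file.path(outdir, "fishplot.tsv")
  write_tsv_with_header(fish, fish_path, hdr)
  add(fish_path, "clone")

  manifest_path <- file.path(outdir, "manifest.tsv")
  write_tsv_with_header(manifest, manifest_path, hdr)
  invisible(manifest)
}
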