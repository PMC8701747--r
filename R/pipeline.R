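#' Default pipeline configuration
#'
#' Collects every fixed analysis constant in one auditable place: fragment
#' size range 20-250 bp, small-fragment cutoff 120 bp, KDE bandwidth
#' 50 bp, copy-number window 1001 bp, kernel variance shrinkage 1/16
#' (size) and 1/4 (position), entropy windows of 1 kb over a 30 kb span,
#' dyad search 10-500 bp from the ACS, and top/bottom 20% efficiency
#' classes for the active/passive entropy comparison.
#'
#' @param ... overrides for any default entry.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    size_range = c(20L, 250L),
    small_fragment_cutoff = 120L,
    kde_bandwidth = 50,
    cn_window = 1001L,
    kernel_shrink_size = 1 / 16,
    kernel_shrink_pos = 1 / 4,
    kernel_halfwidth = 100L,
    entropy_window = 1000L,
    entropy_span = 30000L,
    dyad_search = c(10L, 500L),
    top_fraction = 0.2,
    aggregate_halfspan = 1000L,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [default_config()] entries.
#' @return Named list of parameters.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

#' Write a per-base track as bedGraph
#'
#' Adjacent equal values are collapsed into intervals (0-based half-open).
#'
#' @param track numeric per-base vector.
#' @param chrom chromosome name (default from the track attribute).
#' @param path output path.
#' @param digits signif digits for values.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom = attr(track, "chrom"),
                           digits = 6) {
  if (is.null(chrom)) chrom <- attr(track, "region")$chrom
  v <- signif(as.numeric(track), digits)
  v[is.na(v)] <- 0
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  fwrite(data.table(chrom = chrom, start = starts, end = ends,
                    value = r$values),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Run the full origin-chromatin pipeline on simulated data
#'
#' End-to-end orchestration: simulate a two-replicate cell-cycle time
#' course from a layout, equalize per-size depths within each replicate
#' and merge matched time points, fit the nucleosome kernel on the
#' reference sample's dyad pileup, score copy-number-normalized nucleosome
#' occupancy and calibrated small-fragment footprints per time point,
#' compute the per-origin footprint density table and its efficiency
#' correlation, per-class dyad/NFR dynamics, and the origin-anchored
#' entropy matrices for the most and least efficient origins. Writes all
#' artifacts as plain text plus a manifest with seeds, parameters, and
#' per-file checksums; a rerun with the same config reproduces identical
#' checksums.
#'
#' @param layout a `GenomeLayout`; its planted dyads and Abf1 sites serve
#'   as the reference annotations.
#' @param timepoints from [default_timepoints()]; the first must be the
#'   alpha-factor reference.
#' @param depth fragments per sample.
#' @param outdir output directory (created); `NULL` skips file output.
#' @param config from [default_config()].
#' @return List: `merged` fragment sets, `kernel`, `nuc_tracks`,
#'   `fp` (density table etc.), `rho` (efficiency correlation),
#'   `classes` (per-class summaries), `entropy` (active/passive
#'   `EntropyMatrix`), `manifest`.
#' @export
run_all <- function(layout, timepoints, depth, outdir = NULL,
                    config = default_config()) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (is.null(layout$origins)) stop("config invalid: layout has no origin table")
  sim <- simulate_timecourse(layout, timepoints, depth, replicates = 2,
                             seed = config$seed)
  merged <- equalize_timecourse(sim$fragmentsets, seed = config$seed + 1L,
                                sizes = config$size_range)
  ref_label <- timepoints[[1]]$label
  ref <- merged[[ref_label]]

  dyad_ref <- layout$dyads[layout$dyads$role == "array", c("chrom", "pos")]
  pile <- aggregate_reference_pileup(ref, dyad_ref,
                                     halfwidth = config$kernel_halfwidth,
                                     size_range = config$size_range)
  kernel <- fit_kernel(pile, shrink_size = config$kernel_shrink_size,
                       shrink_pos = config$kernel_shrink_pos)

  origins <- layout_origins(layout)
  chroms <- unique(origins$chrom)
  nuc_tracks <- list()
  for (tp in names(merged)) {
    trs <- list()
    for (cn in chroms) {
      L <- layout$chrom_lengths[[cn]]
      tr <- nucleosome_track(merged[[tp]], kernel, cn, L)
      cnr <- if (identical(tp, ref_label)) 1 else
        compute_copy_number(merged[[tp]], ref, cn, L,
                            window = config$cn_window)
      trs[[cn]] <- normalize_track(tr, cnr)
    }
    nuc_tracks[[tp]] <- trs
  }

  fp <- footprint_density_table(merged, layout$chrom_lengths, origins,
                                abf1_sites = layout$abf1_sites,
                                bandwidth = config$kde_bandwidth,
                                cn_window = config$cn_window,
                                ref_label = ref_label)
  rho <- efficiency_correlation(fp$density, origins$efficiency)
  classes <- origin_class_summary(nuc_tracks, fp$tracks, origins,
                                  halfspan = config$aggregate_halfspan,
                                  search = config$dyad_search)

  eff_rank <- rank(origins$efficiency, ties.method = "first")
  k <- max(1L, floor(config$top_fraction * nrow(origins)))
  active <- origins[which(eff_rank > nrow(origins) - k), ]
  passive <- origins[which(eff_rank <= k), ]
  ent <- list(
    active = entropy_heatmap(nuc_tracks, active,
                             window = config$entropy_window,
                             span = config$entropy_span),
    passive = entropy_heatmap(nuc_tracks, passive,
                              window = config$entropy_window,
                              span = config$entropy_span))

  manifest <- list(package_version = as.character(utils::packageVersion("oricycle")),
                   seed = config$seed,
                   parameters = config[order(names(config))],
                   sample_seeds = as.list(sim$truth$seeds))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (tp in names(merged))
      write_fragments(merged[[tp]], file.path(outdir, paste0(tp, ".bed")))
    fwrite(data.table(origin = rownames(fp$density), fp$density),
           file.path(outdir, "footprint_density.tsv"), sep = "\t")
    fwrite(rho, file.path(outdir, "efficiency_rho.tsv"), sep = "\t")
    for (cl in names(classes))
      fwrite(classes[[cl]]$dyads,
             file.path(outdir, paste0("dyads_", gsub("[^A-Za-z0-9]", "", cl),
                                      ".tsv")), sep = "\t")
    for (set in names(ent))
      utils::write.table(ent[[set]],
                         file.path(outdir, paste0("entropy_", set, ".tsv")),
                         sep = "\t", quote = FALSE, col.names = NA)
    files <- list.files(outdir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(merged = merged, kernel = kernel, nuc_tracks = nuc_tracks, fp = fp,
       rho = rho, classes = classes, entropy = ent, manifest = manifest)
}
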