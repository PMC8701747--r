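#' Read an origin annotation table
#'
#' Tab-separated table with columns `name`, `chrom`, `acs` (0-based ACS
#' position), `strand` (T-rich strand, + or -), `class` ("G1&G2",
#' "G1only" or empty) and `efficiency` (0-1, may be missing).
#'
#' @param path TSV path with a header line.
#' @return data.table of origin annotations.
#' @export
read_origins <- function(path) {
  o <- fread(path, sep = "\t", header = TRUE)
  need <- c("name", "chrom", "acs", "strand")
  miss <- setdiff(need, names(o))
  if (length(miss)) stop("origin table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(o$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if ("efficiency" %in% names(o) &&
      any(!is.na(o$efficiency) & (o$efficiency < 0 | o$efficiency > 1)))
    stop("efficiency must lie in [0, 1]")
  o
}

#' Extract an origin table from a synthetic layout
#'
#' @param layout a `GenomeLayout`.
#' @return data.table with the columns of [read_origins()].
#' @export
layout_origins <- function(layout) {
  o <- layout$origins
  if (is.null(o)) stop("layout has no origins")
  o[, list(name, chrom, acs, strand, class, efficiency)]
}

#' ACS-oriented aggregate profile around origins
#'
#' Extracts a +/-`halfspan` window of a per-base track around each origin
#' ACS, flips windows of minus-strand origins so all origins read in
#' T-rich orientation (upstream left, +1 nucleosome right), and averages.
#' Origins too close to a chromosome end are skipped.
#'
#' @param tracks named list chromosome -> numeric per-base track.
#' @param origins origin table (`chrom`, `acs`, `strand`).
#' @param halfspan window half-width (bp).
#' @return Numeric vector of length `2*halfspan + 1`, names = offsets
#'   -halfspan..halfspan from the ACS; attribute `n` = origins used.
#' @export
orient_and_aggregate <- function(tracks, origins, halfspan = 1000L) {
  prof <- numeric(2L * halfspan + 1L)
  n <- 0L
  for (i in seq_len(nrow(origins))) {
    tr <- tracks[[origins$chrom[i]]]
    if (is.null(tr)) next
    lo <- origins$acs[i] - halfspan
    hi <- origins$acs[i] + halfspan
    if (lo < 0 || hi >= length(tr)) next
    w <- as.numeric(tr[(lo + 1L):(hi + 1L)])
    if (origins$strand[i] == "-") w <- rev(w)
    prof <- prof + w
    n <- n + 1L
  }
  if (n == 0L) stop("no origin window fits inside its chromosome")
  structure(prof / n, names = (-halfspan):halfspan, n = n)
}

#' Call -1/+1 nucleosome dyads and NFR width around the ACS
#'
#' The +1 (-1) dyad is the position of maximal nucleosome score
#' downstream (upstream) of the ACS within the search window, in T-rich
#' orientation; ties break toward the ACS (the innermost nucleosome is
#' the named +1/-1). The NFR width is the dyad-to-dyad distance.
#'
#' @param profile oriented profile from [orient_and_aggregate()] (names =
#'   offsets from the ACS), or any numeric vector with offset names.
#' @param search `c(min, max)` distance from the ACS searched on each side
#'   (bp, default 10-500).
#' @return A `DyadCall` list: `minus_one` (< 0), `plus_one` (> 0),
#'   `nfr_width = plus_one - minus_one`, `low_confidence` (flat window).
#' @export
call_dyads <- function(profile, search = c(10L, 500L)) {
  offs <- as.integer(names(profile))
  if (is.null(offs)) stop("profile must carry offset names")
  up <- which(offs >= -search[2] & offs <= -search[1])
  dn <- which(offs >= search[1] & offs <= search[2])
  if (!length(up) || !length(dn))
    stop("profile does not cover the search window")
  flat <- (max(profile[up]) == min(profile[up])) ||
    (max(profile[dn]) == min(profile[dn]))
  # ties toward the ACS: upstream -> last max; downstream -> first max
  vu <- as.numeric(profile[up])
  minus_one <- offs[up][max(which(vu == max(vu)))]
  vd <- as.numeric(profile[dn])
  plus_one <- offs[dn][min(which(vd == max(vd)))]
  structure(list(minus_one = minus_one, plus_one = plus_one,
                 nfr_width = plus_one - minus_one,
                 low_confidence = flat),
            class = "DyadCall")
}

#' Average footprint occupancy around the class aggregate peak
#'
#' Locates the peak of the time-averaged aggregate footprint profile of an
#' origin class (fixed across time points) and returns the mean occupancy
#' within +/-`halfwidth` of that peak at each time point.
#'
#' @param profiles matrix offsets x time points (rownames = offsets from
#'   the ACS), e.g. columns from [orient_and_aggregate()] per time point.
#' @param halfwidth averaging half-width (bp, default 100).
#' @return Named numeric vector: one average per time point; attribute
#'   `peak_offset`.
#' @export
footprint_peak_average <- function(profiles, halfwidth = 100L) {
  offs <- as.integer(rownames(profiles))
  avg <- rowMeans(profiles)
  peak <- offs[which.max(avg)]
  sel <- which(offs >= peak - halfwidth & offs <= peak + halfwidth)
  structure(colMeans(profiles[sel, , drop = FALSE]), peak_offset = peak)
}

#' Spearman correlation between footprint density and origin efficiency
#'
#' For each time point, the Spearman rank correlation across origins
#' between log2-transformed ACS footprint density and activation
#' efficiency. Densities are offset by epsilon = half the smallest
#' positive density before the log (zero-handling; the transform is
#' rank-preserving for positive densities, so epsilon matters only for
#' zeros). Origins with missing efficiency are excluded pairwise.
#'
#' @param density matrix origins x time points (from
#'   [footprint_density_table()]).
#' @param efficiency numeric vector of origin efficiencies, aligned with
#'   `density` rows.
#' @return data.table: `timepoint`, `rho`, `n`; `rho` is `NA` (flagged)
#'   when either variable has zero variance.
#' @export
efficiency_correlation <- function(density, efficiency) {
  stopifnot(nrow(density) == length(efficiency))
  pos <- density[density > 0 & !is.na(density)]
  eps <- if (length(pos)) min(pos) * 0.5 else 1e-9
  out <- data.table(timepoint = colnames(density), rho = NA_real_,
                    n = 0L)
  for (j in seq_len(ncol(density))) {
    d <- density[, j]
    ok <- !is.na(d) & !is.na(efficiency)
    out$n[j] <- sum(ok)
    if (sum(ok) < 3) next
    x <- log2(d[ok] + eps); y <- efficiency[ok]
    if (sd(x) == 0 || sd(y) == 0) next
    out$rho[j] <- cor(x, y, method = "spearman")
  }
  out
}

#' Per-class, per-time-point origin summaries
#'
#' Convenience wrapper producing the origin-level outputs of the pipeline:
#' oriented aggregate nucleosome and footprint profiles per footprint
#' class at each time point, aggregate -1/+1 dyad calls and NFR widths,
#' and the +/-100 bp footprint peak averages.
#'
#' @param nuc_tracks,fp_tracks named lists time point -> chromosome ->
#'   per-base track.
#' @param origins origin table with `class` column.
#' @param halfspan aggregation half-span (bp).
#' @param search dyad search window, see [call_dyads()].
#' @return List per class: `nuc_profiles`, `fp_profiles` (offset x time
#'   matrices), `dyads` (data.table per time point), `peak_avg`.
#' @export
origin_class_summary <- function(nuc_tracks, fp_tracks, origins,
                                 halfspan = 1000L, search = c(10L, 500L)) {
  out <- list()
  tps <- names(nuc_tracks)
  for (cl in setdiff(unique(origins$class), c(NA, ""))) {
    keep <- !is.na(origins$class) & origins$class == cl
    oo <- origins[which(keep), ]
    nucp <- sapply(tps, function(tp)
      orient_and_aggregate(nuc_tracks[[tp]], oo, halfspan))
    fpp <- sapply(tps, function(tp)
      orient_and_aggregate(fp_tracks[[tp]], oo, halfspan))
    rownames(nucp) <- rownames(fpp) <- (-halfspan):halfspan
    dy <- data.table::rbindlist(lapply(tps, function(tp) {
      dc <- call_dyads(nucp[, tp], search)
      data.table(timepoint = tp, minus_one = dc$minus_one,
                 plus_one = dc$plus_one, nfr_width = dc$nfr_width,
                 low_confidence = dc$low_confidence)
    }))
    out[[cl]] <- list(nuc_profiles = nucp, fp_profiles = fpp, dyads = dy,
                      peak_avg = footprint_peak_average(fpp))
  }
  out
}
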