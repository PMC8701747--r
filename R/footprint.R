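#' Small-fragment footprint occupancy track
#'
#' Estimates the per-base midpoint density of fragments smaller than
#' 120 bp (strict) with a Gaussian kernel of bandwidth 50 bp — bandwidth
#' here meaning the SD of the Gaussian kernel, not its FWHM — and scales
#' the density by the chromosome length, so an unstructured chromosome has
#' mean occupancy ~1. The density is estimated per chromosome
#' (conditioned on the chromosome).
#'
#' The KDE is computed exactly for integer midpoints: the per-bp midpoint
#' histogram is convolved with a discrete Gaussian (truncated at 4 SD,
#' renormalized to unit mass) and divided by the number of qualifying
#' fragments.
#'
#' @param fs a `FragmentSet`.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length (bp).
#' @param bandwidth Gaussian kernel SD in bp (default 50).
#' @param max_size fragments with `length < max_size` qualify (default 120).
#' @return A `FootprintTrack` numeric vector of length `chrom_length`
#'   (attributes `chrom`, `kind = "footprint"`, `n_fragments`). All zeros,
#'   with a warning, if no fragment qualifies.
#' @export
small_fragment_track <- function(fs, chrom, chrom_length, bandwidth = 50,
                                 max_size = 120L) {
  stopifnot(bandwidth > 0)
  keep <- fs$chrom == chrom & fs$length < max_size &
    fs$midpoint >= 0L & fs$midpoint < chrom_length
  mids <- fs$midpoint[keep]
  n <- length(mids)
  if (n == 0L) {
    warning("no fragments smaller than ", max_size, " bp on ", chrom)
    return(structure(numeric(chrom_length), chrom = chrom,
                     kind = "footprint", n_fragments = 0L,
                     class = "FootprintTrack"))
  }
  h <- ceiling(4 * bandwidth)
  kern <- dnorm((-h):h, 0, bandwidth)
  kern <- kern / sum(kern)
  hist <- tabulate(mids + 1L, nbins = chrom_length)
  padded <- c(numeric(h), hist, numeric(h))
  sm <- stats::filter(padded, rev(kern), method = "convolution", sides = 2)
  dens <- as.numeric(sm[(h + 1L):(h + chrom_length)]) / n
  structure(dens * chrom_length, chrom = chrom, kind = "footprint",
            n_fragments = n, class = "FootprintTrack")
}

#' MNase-digestion scale factor from Abf1p binding sites
#'
#' The reciprocal of the average small-fragment occupancy within +/-100 bp
#' of a set of Abf1p binding sites. Abf1p occupancy is cell-cycle
#' invariant, so this factor calibrates away sample-specific MNase
#' digestion and depth differences when applied multiplicatively per time
#' point. Every base in every window contributes equally; windows clipped
#' at chromosome ends contribute their covered bases.
#'
#' @param tracks a `FootprintTrack`, or a named list of them (by
#'   chromosome) when sites span several chromosomes.
#' @param sites data.frame with columns `chrom`, `pos` (0-based site
#'   positions).
#' @param halfwidth window half-width around each site (bp, default 100).
#' @return Scalar scale factor (1 / aggregate mean).
#' @export
abf1_scale_factor <- function(tracks, sites, halfwidth = 100L) {
  if (inherits(tracks, "FootprintTrack"))
    tracks <- setNames(list(tracks), attr(tracks, "chrom"))
  vals <- numeric(0)
  for (i in seq_len(nrow(sites))) {
    tr <- tracks[[sites$chrom[i]]]
    if (is.null(tr)) next
    lo <- max(sites$pos[i] - halfwidth, 0L)
    hi <- min(sites$pos[i] + halfwidth, length(tr) - 1L)
    if (hi < lo) next
    vals <- c(vals, as.numeric(tr[(lo + 1L):(hi + 1L)]))
  }
  if (!length(vals)) stop("no Abf1 site overlaps a scored chromosome")
  m <- mean(vals)
  if (m <= 0) stop("aggregate Abf1 occupancy is zero: calibration impossible")
  1 / m
}

#' Footprint density at an origin's ACS
#'
#' Reads the (calibrated, copy-number-normalized) small-fragment occupancy
#' track at the ACS anchor base of an origin.
#'
#' @param track a `FootprintTrack` for the origin's chromosome.
#' @param origin one-row data.frame/list with `chrom` and `acs` (0-based).
#' @param average_halfwidth optional half-width to average over instead of
#'   reading the single ACS base (default 0 = single base).
#' @return Scalar density.
#' @export
acs_footprint_density <- function(track, origin, average_halfwidth = 0L) {
  pos <- origin$acs
  if (pos < 0 || pos >= length(track)) stop("ACS position out of bounds")
  if (average_halfwidth == 0L) return(as.numeric(track[pos + 1L]))
  lo <- max(pos - average_halfwidth, 0L)
  hi <- min(pos + average_halfwidth, length(track) - 1L)
  mean(as.numeric(track[(lo + 1L):(hi + 1L)]))
}

#' Calibrated footprint tracks and per-origin density table
#'
#' For each time point: small-fragment KDE track per chromosome,
#' copy-number normalization against the reference sample, Abf1p
#' calibration (factor computed on the copy-number-normalized track), then
#' the per-origin density read at each ACS.
#'
#' @param fsets named list of merged `FragmentSet`s by time point; the
#'   first (or `ref_label`) is the alpha-factor reference.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param origins origin table (`name`, `chrom`, `acs`, ...).
#' @param abf1_sites data.frame (`chrom`, `pos`) or NULL to skip calibration.
#' @param bandwidth KDE bandwidth (bp).
#' @param cn_window copy-number window (bp).
#' @param ref_label label of the reference sample (default first).
#' @return List: `density` (matrix origins x time points), `tracks`
#'   (list time point -> chrom -> calibrated `FootprintTrack`),
#'   `scale_factors` (per time point).
#' @export
footprint_density_table <- function(fsets, chrom_lengths, origins,
                                    abf1_sites = NULL, bandwidth = 50,
                                    cn_window = 1001L,
                                    ref_label = names(fsets)[1]) {
  ref <- fsets[[ref_label]]
  dens <- matrix(NA_real_, nrow = nrow(origins), ncol = length(fsets),
                 dimnames = list(origins$name, names(fsets)))
  tracks <- list(); sfs <- setNames(numeric(length(fsets)), names(fsets))
  for (tp in names(fsets)) {
    fs <- fsets[[tp]]
    trs <- list()
    for (cn in unique(origins$chrom)) {
      L <- chrom_lengths[[cn]]
      tr <- small_fragment_track(fs, cn, L, bandwidth = bandwidth)
      cnr <- if (identical(tp, ref_label)) 1 else
        compute_copy_number(fs, ref, cn, L, window = cn_window)
      trs[[cn]] <- normalize_track(tr, cnr)
    }
    sf <- if (!is.null(abf1_sites)) abf1_scale_factor(trs, abf1_sites) else 1
    sfs[tp] <- sf
    trs <- lapply(trs, function(t) {
      out <- as.numeric(t) * sf
      attributes(out) <- attributes(t)
      attr(out, "abf1_calibrated") <- !is.null(abf1_sites)
      out
    })
    tracks[[tp]] <- trs
    for (i in seq_len(nrow(origins)))
      dens[i, tp] <- acs_footprint_density(trs[[origins$chrom[i]]],
                                           origins[i, ])
  }
  list(density = dens, tracks = tracks, scale_factors = sfs)
}
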