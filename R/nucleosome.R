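#' Aggregate fragment pileup around reference nucleosome dyads
#'
#' Stacks fragment midpoints at offsets from each reference dyad into a
#' (fragment size x midpoint offset) matrix — the empirical size/coverage
#' distribution of MNase-seq reads centered at a canonical well-positioned
#' nucleosome. Offsets are oriented uniformly (nucleosomes are unstranded).
#'
#' @param fs a `FragmentSet`.
#' @param dyads data.frame with columns `chrom`, `pos` (0-based dyad
#'   positions), e.g. a chemical-map dyad list.
#' @param halfwidth half-width W of the offset window (bp); offsets run
#'   -W..+W.
#' @param size_range inclusive fragment-size range.
#' @return Integer matrix (sizes x offsets) with dimnames.
#' @export
aggregate_reference_pileup <- function(fs, dyads, halfwidth = 100L,
                                       size_range = c(20L, 250L)) {
  stopifnot(halfwidth > 0, nrow(dyads) >= 1)
  sizes <- size_range[1]:size_range[2]
  offsets <- (-halfwidth):halfwidth
  m <- matrix(0L, nrow = length(sizes), ncol = length(offsets),
              dimnames = list(size = sizes, offset = offsets))
  dd <- as.data.table(dyads)
  keepf <- fs$length >= size_range[1] & fs$length <= size_range[2]
  sub <- fs[which(keepf)]
  skipped <- 0L
  for (cn in unique(dd$chrom)) {
    fsel <- which(sub$chrom == cn)
    if (!length(fsel)) { skipped <- skipped + sum(dd$chrom == cn); next }
    mids <- sub$midpoint[fsel]; lens <- sub$length[fsel]
    ord <- order(mids)
    mids <- mids[ord]; lens <- lens[ord]
    for (p in dd$pos[dd$chrom == cn]) {
      lo <- findInterval(p - halfwidth - 1L, mids) + 1L
      hi <- findInterval(p + halfwidth, mids)
      if (hi < lo) next
      i <- lens[lo:hi] - size_range[1] + 1L
      j <- mids[lo:hi] - p + halfwidth + 1L
      cnt <- data.table(i = i, j = j)[, .N, by = list(i, j)]
      m[cbind(cnt$i, cnt$j)] <- m[cbind(cnt$i, cnt$j)] + cnt$N
    }
  }
  if (skipped) message(skipped, " dyads on chromosomes without fragments skipped")
  m
}

#' Fit the 2D nucleosome kernel from a dyad pileup
#'
#' Computes count-weighted marginal means and variances of the pileup in
#' the midpoint-offset and fragment-size dimensions, then builds a
#' bivariate Gaussian (zero correlation, separable) on the same grid with
#' the size variance shrunk to 1/16 and the position variance shrunk to
#' 1/4 of the marginal values. The kernel is truncated to the grid and
#' renormalized to sum 1, so cross-correlation scores are comparable
#' across kernels.
#'
#' @param pileup matrix from [aggregate_reference_pileup()] (sizes x offsets).
#' @param shrink_size,shrink_pos variance shrinkage factors.
#' @return A `NucleosomeKernel`: list with `weights` (sizes x offsets,
#'   sums to 1), `params` (mu/sigma2 per dimension), and the grids.
#' @export
fit_kernel <- function(pileup, shrink_size = 1 / 16, shrink_pos = 1 / 4) {
  tot <- sum(pileup)
  if (tot <= 0) stop("empty pileup: cannot fit a kernel")
  sizes <- as.numeric(rownames(pileup))
  offsets <- as.numeric(colnames(pileup))
  ms <- rowSums(pileup); mo <- colSums(pileup)
  mu_size <- sum(sizes * ms) / tot
  mu_pos <- sum(offsets * mo) / tot
  var_size <- sum((sizes - mu_size)^2 * ms) / tot
  var_pos <- sum((offsets - mu_pos)^2 * mo) / tot
  if (var_size <= 0 || var_pos <= 0)
    stop("degenerate pileup: zero marginal variance")
  s2_size <- var_size * shrink_size
  s2_pos <- var_pos * shrink_pos
  g <- dnorm(sizes, mu_size, sqrt(s2_size))
  f <- dnorm(offsets, mu_pos, sqrt(s2_pos))
  w <- outer(g, f)
  w <- w / sum(w)
  dimnames(w) <- dimnames(pileup)
  structure(list(weights = w,
                 params = list(mu_size = mu_size, mu_pos = mu_pos,
                               sigma2_size = s2_size, sigma2_pos = s2_pos,
                               marginal_var_size = var_size,
                               marginal_var_pos = var_pos,
                               shrink_size = shrink_size,
                               shrink_pos = shrink_pos),
                 sizes = sizes, offsets = offsets),
            class = "NucleosomeKernel")
}

#' @export
print.NucleosomeKernel <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("NucleosomeKernel: mu_size %.1f bp (sigma %.1f), ",
                     "mu_pos %+.1f bp (sigma %.1f); grid %dx%d\n"),
              p$mu_size, sqrt(p$sigma2_size), p$mu_pos, sqrt(p$sigma2_pos),
              length(x$sizes), length(x$offsets)))
  invisible(x)
}

#' Score nucleosome occupancy by kernel cross-correlation
#'
#' The nucleosome score at position p is the cross-correlation of the
#' local fragment size-by-midpoint counts with the model kernel:
#' `score(p) = sum over (offset, size) of kernel(size, offset) *
#' counts(size, p + offset)`. Positions within W of the region boundary
#' are scored against the zero-padded window.
#'
#' @param vplot a `VPlotMatrix` from [build_vplot()].
#' @param kernel a `NucleosomeKernel`.
#' @return An `OccupancyTrack`: numeric vector over the region's positions
#'   with `region` and `kind = "nucleosome"` attributes.
#' @export
score_nucleosomes <- function(vplot, kernel) {
  sizes <- as.integer(rownames(vplot))
  ksz <- as.integer(rownames(kernel$weights))
  if (min(ksz) < min(sizes) || max(ksz) > max(sizes))
    stop("vplot size range does not cover kernel size range")
  rows <- match(ksz, sizes)
  # the kernel is a separable product Gaussian with total mass 1, so its
  # marginals factorize it exactly: weights == outer(rowSums, colSums);
  # the 2D cross-correlation reduces to a size-weighted column sum
  # followed by a 1D cross-correlation over offsets
  gw <- rowSums(kernel$weights)
  wvec <- as.vector(gw %*% vplot[rows, , drop = FALSE])
  score <- xcorr1d(wvec, kernel)
  structure(score, region = attr(vplot, "region"), kind = "nucleosome",
            class = "OccupancyTrack")
}

# 1D cross-correlation of a per-base vector with the kernel's positional
# marginal (offsets -W..W), zero-padded at the edges
xcorr1d <- function(wvec, kernel) {
  fw <- colSums(kernel$weights)
  offs <- as.integer(colnames(kernel$weights))
  W <- max(offs)
  stopifnot(identical(offs, (-W):W))
  padded <- c(numeric(W), wvec, numeric(W))
  y <- stats::filter(padded, rev(fw), method = "convolution", sides = 2)
  as.numeric(y[(W + 1L):(W + length(wvec))])
}

#' Replication copy number from windowed RPKM ratios
#'
#' The copy number of a position at time t is the ratio of the RPKM of all
#' fragments in a 1001 bp window centered there to the RPKM of the same
#' window in the alpha-factor (G1) reference sample. RPKM counts fragment
#' midpoints in the window, divided by window length in kb and sample
#' total in millions. Windows clipped at chromosome ends use the actual
#' covered width. Positions where the reference window is empty get `NA`
#' (never +/-Inf).
#'
#' @param fs_t,fs_ref `FragmentSet`s for the time point and the
#'   alpha-factor reference.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length (bp).
#' @param window window width in bp (odd; default 1001).
#' @param positions optional 0-based positions to evaluate; default all
#'   bases.
#' @return A `CopyNumberTrack` numeric vector over `positions` (attributes
#'   `chrom`, `kind = "copy-number"`).
#' @export
compute_copy_number <- function(fs_t, fs_ref, chrom, chrom_length,
                                window = 1001L, positions = NULL) {
  if (nrow(fs_t) == 0 || nrow(fs_ref) == 0) stop("empty FragmentSet")
  if (window %% 2L != 1L) stop("window must be odd")
  h <- (window - 1L) %/% 2L
  win_counts <- function(fs) {
    cc <- cumsum(midpoint_counts(fs, chrom, chrom_length))
    p <- if (is.null(positions)) 0:(chrom_length - 1L) else positions
    lo <- pmax(p - h, 0L)
    hi <- pmin(p + h, chrom_length - 1L)
    cnt <- cc[hi + 1L] - ifelse(lo > 0L, cc[lo], 0)
    list(count = cnt, width = hi - lo + 1L)
  }
  wt <- win_counts(fs_t); wr <- win_counts(fs_ref)
  rpkm_t <- wt$count / (wt$width / 1000) / (nrow(fs_t) / 1e6)
  rpkm_r <- wr$count / (wr$width / 1000) / (nrow(fs_ref) / 1e6)
  ratio <- ifelse(wr$count > 0, rpkm_t / rpkm_r, NA_real_)
  structure(ratio, chrom = chrom, kind = "copy-number",
            class = "CopyNumberTrack")
}

#' Normalize an occupancy track by copy number
#'
#' Divides per-base scores by the copy-number ratio. Non-positive or
#' missing copy numbers propagate `NA` at that position.
#'
#' @param track numeric score vector (e.g. from [score_nucleosomes()]).
#' @param cn copy-number vector of the same length (or a scalar).
#' @return Track of the same shape with scores divided by copy number.
#' @export
normalize_track <- function(track, cn) {
  if (length(cn) != 1L && length(cn) != length(track))
    stop("copy-number track length mismatch")
  cnv <- as.numeric(cn)
  cnv[!is.na(cnv) & cnv <= 0] <- NA_real_
  out <- as.numeric(track) / if (length(cnv) == 1L) rep(cnv, length(track)) else cnv
  attributes(out) <- attributes(track)
  attr(out, "cn_normalized") <- TRUE
  out
}

#' Genome-wide nucleosome score track for one chromosome
#'
#' Convenience wrapper: builds the V-plot over the whole chromosome and
#' cross-correlates with the kernel.
#'
#' @inheritParams compute_copy_number
#' @param fs a `FragmentSet`.
#' @param kernel a `NucleosomeKernel`.
#' @return `OccupancyTrack` of length `chrom_length`.
#' @export
nucleosome_track <- function(fs, kernel, chrom, chrom_length) {
  ksz <- as.integer(rownames(kernel$weights))
  gw <- rowSums(kernel$weights)
  keep <- fs$chrom == chrom & fs$length >= min(ksz) & fs$length <= max(ksz) &
    fs$midpoint >= 0L & fs$midpoint < chrom_length
  mids <- fs$midpoint[keep]
  w <- gw[match(fs$length[keep], ksz)]
  wvec <- numeric(chrom_length)
  if (length(mids)) {
    agg <- data.table(mid = mids, w = w)[, list(w = sum(w)), by = mid]
    wvec[agg$mid + 1L] <- agg$w
  }
  score <- xcorr1d(wvec, kernel)
  structure(score, region = list(chrom = chrom, start = 0L, end = chrom_length),
            kind = "nucleosome", class = "OccupancyTrack")
}
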