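#' Shannon entropy of nucleosome organization in a window
#'
#' For a region X of n bases with nonnegative nucleosome scores, the
#' per-base probability is `P(x_i) = nuc_i / sum(nuc)` and the
#' disorganization is the Shannon entropy
#' `H(X) = -sum P(x_i) log P(x_i)` (natural log, with 0 log 0 := 0 by
#' continuity). Well-positioned nucleosomes concentrate score mass and
#' give low entropy; fuzzy, disorganized nucleosomes approach the uniform
#' maximum log(n). Windows with zero total score return `NA` (absence of
#' signal is not "organized").
#'
#' @param scores numeric vector of nonnegative per-base nucleosome scores.
#' @return Scalar entropy in nats, in `[0, log(length(scores))]`, or `NA`.
#' @export
window_entropy <- function(scores) {
  scores <- as.numeric(scores)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(NA_real_)
  if (any(scores < 0)) stop("negative scores: not a valid probability construction")
  tot <- sum(scores)
  if (tot <= 0) return(NA_real_)
  p <- scores / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Origin-anchored entropy matrix across the time course
#'
#' Tiles the 30 kb surrounding each origin ACS into 1 kb windows, computes
#' the Shannon entropy of the copy-number-normalized nucleosome score in
#' each window at every time point, pools windows across origins by the
#' absolute distance of the window center from the ACS, and z-scores each
#' distance row across time points. Rising z-entropy marks the transient
#' nucleosome disorganization carried by the passing replication fork;
#' with forks moving outward, distal rows peak later than proximal rows.
#'
#' @param tracks named list (time point -> chromosome -> numeric
#'   nucleosome score track covering the chromosome).
#' @param origins origin table with `chrom`, `acs`.
#' @param window window size in bp (default 1000).
#' @param span total span around each ACS in bp (default 30000).
#' @param zscore z-score rows (default TRUE).
#' @return An `EntropyMatrix`: matrix distance-bin x time point, rows
#'   labeled by bin center distance (bp). Attributes: `raw` (pre-z-score
#'   means), `per_origin` (origins x window x time array),
#'   `zero_variance` (logical per row).
#' @export
entropy_heatmap <- function(tracks, origins, window = 1000L, span = 30000L,
                            zscore = TRUE) {
  tps <- names(tracks)
  if (length(tps) < 2 && zscore)
    stop("z-scoring needs >= 2 time points")
  nwin <- span %/% window
  half <- span %/% 2L
  # window start offsets relative to the ACS
  offs <- seq(-half, by = window, length.out = nwin)
  centers <- offs + window / 2
  per_origin <- array(NA_real_,
                      dim = c(nrow(origins), nwin, length(tps)),
                      dimnames = list(origins$name, round(centers), tps))
  for (t in seq_along(tps)) {
    for (i in seq_len(nrow(origins))) {
      tr <- tracks[[t]][[origins$chrom[i]]]
      if (is.null(tr)) next
      for (w in seq_len(nwin)) {
        lo <- origins$acs[i] + offs[w]
        hi <- lo + window - 1L
        if (lo < 0 || hi >= length(tr)) next
        per_origin[i, w, t] <- window_entropy(tr[(lo + 1L):(hi + 1L)])
      }
    }
  }
  dist_bin <- abs(centers)
  bins <- sort(unique(dist_bin))
  raw <- matrix(NA_real_, nrow = length(bins), ncol = length(tps),
                dimnames = list(distance = bins, timepoint = tps))
  for (b in seq_along(bins)) {
    sel <- which(dist_bin == bins[b])
    for (t in seq_along(tps))
      raw[b, t] <- mean(per_origin[, sel, t], na.rm = TRUE)
  }
  zv <- rep(FALSE, length(bins))
  out <- raw
  if (zscore) {
    for (b in seq_along(bins)) {
      s <- sd(raw[b, ], na.rm = TRUE)
      if (is.na(s) || s == 0) { out[b, ] <- 0; zv[b] <- TRUE }
      else out[b, ] <- (raw[b, ] - mean(raw[b, ], na.rm = TRUE)) / s
    }
  }
  structure(out, raw = raw, per_origin = per_origin, zero_variance = zv,
            class = c("EntropyMatrix", "matrix", "array"))
}
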