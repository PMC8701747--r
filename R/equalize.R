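#' Per-fragment-size depth table across time points
#'
#' For one replicate's time-point series, counts fragments of each size in
#' `sizes[1]:sizes[2]` per sample and records the minimum count per size
#' across samples — the subsampling depth that equalizes sequencing depth
#' and MNase digestion bias between time points.
#'
#' @param fragmentsets list of `FragmentSet`s (one per time point, same
#'   replicate), exclusions already applied.
#' @param sizes inclusive fragment-size range, default `c(20, 250)`.
#' @return A `SizeDepthTable`: list with `counts` (matrix size x sample),
#'   `min` (named vector, the per-size minimum) and `sizes`.
#' @export
compute_depths <- function(fragmentsets, sizes = c(20L, 250L)) {
  if (sizes[2] < sizes[1]) stop("empty size range")
  if (!length(fragmentsets)) stop("need at least one FragmentSet")
  svec <- sizes[1]:sizes[2]
  counts <- vapply(fragmentsets, function(fs) {
    lens <- fs$length[fs$length >= sizes[1] & fs$length <= sizes[2]]
    tabulate(lens - sizes[1] + 1L, nbins = length(svec))
  }, integer(length(svec)))
  counts <- matrix(counts, nrow = length(svec),
                   dimnames = list(size = svec,
                                   sample = vapply(fragmentsets, fs_label, "")))
  structure(list(counts = counts,
                 min = setNames(apply(counts, 1, min), svec),
                 sizes = sizes),
            class = "SizeDepthTable")
}

#' Subsample a fragment set to the per-size minimum depth
#'
#' For every fragment size s in the table's range, exactly `min_s`
#' fragments are retained, drawn uniformly without replacement, so that
#' after subsampling every time point carries an identical number of
#' fragments of each length. Fragments outside the size range are dropped.
#' Draws are deterministic given `seed`; each size uses its own derived
#' seed so per-size draws are independent and reproducible.
#'
#' @param fs a `FragmentSet`.
#' @param table a `SizeDepthTable` from [compute_depths()].
#' @param seed integer master seed.
#' @return Subsampled `FragmentSet` (a subset of the input rows).
#' @export
subsample <- function(fs, table, seed) {
  sizes <- table$sizes
  keep_idx <- integer(0)
  for (s in sizes[1]:sizes[2]) {
    m <- table$min[[as.character(s)]]
    if (m == 0L) next
    at <- which(fs$length == s)
    if (m > length(at))
      stop("size ", s, ": requested ", m, " > available ", length(at))
    set.seed(as.integer((as.numeric(seed) * 69091 + s) %% 2147483647))
    keep_idx <- c(keep_idx, if (m == length(at)) at else sample(at, m))
  }
  out <- fs[sort(keep_idx)]
  fragment_set(out, fs_label(fs),
               c(attr(fs, "provenance"),
                 sprintf("subsampled to per-size minimum depth (seed %d)",
                         as.integer(seed))))
}

#' Merge matched time points between replicates
#'
#' Concatenates two fragment sets for the same time point (replicate
#' merging after per-replicate subsampling).
#'
#' @param rep1,rep2 `FragmentSet`s whose labels share the time-point prefix
#'   (label up to the last `.`-separated token), or identical labels.
#' @param label label of the merged set; default, the shared time point.
#' @return Merged `FragmentSet` with provenance recording both sources.
#' @export
merge_matched <- function(rep1, rep2, label = NULL) {
  tp1 <- sub("\\.[^.]*$", "", fs_label(rep1))
  tp2 <- sub("\\.[^.]*$", "", fs_label(rep2))
  if (!identical(tp1, tp2) && !identical(fs_label(rep1), fs_label(rep2)))
    stop("time-point label mismatch: '", fs_label(rep1), "' vs '",
         fs_label(rep2), "'")
  if (is.null(label)) label <- tp1
  common <- intersect(names(rep1), names(rep2))
  merged <- data.table::rbindlist(list(rep1[, common, with = FALSE],
                                       rep2[, common, with = FALSE]))
  fragment_set(merged, label,
               c(paste0("merged: ", fs_label(rep1)),
                 paste0("merged: ", fs_label(rep2))))
}

#' Equalize and merge a two-replicate time course
#'
#' Runs the depth-equalization recipe: per replicate, compute the per-size
#' minimum depth across its time points and subsample every time point to
#' it; then merge matched time points between replicates.
#'
#' @param fsets named list of `FragmentSet`s labeled `"<tp>.rep<k>"`.
#' @param seed master seed for subsampling.
#' @param sizes inclusive size range.
#' @return Named list of merged `FragmentSet`s, one per time point, in
#'   first-seen time-point order.
#' @export
equalize_timecourse <- function(fsets, seed, sizes = c(20L, 250L)) {
  labs <- vapply(fsets, fs_label, "")
  rep_of <- sub("^.*\\.", "", labs)
  tp_of <- sub("\\.[^.]*$", "", labs)
  subs <- vector("list", length(fsets))
  names(subs) <- labs
  for (r in unique(rep_of)) {
    sel <- which(rep_of == r)
    tab <- compute_depths(fsets[sel], sizes)
    for (k in seq_along(sel)) {
      i <- sel[k]
      subs[[i]] <- subsample(fsets[[i]],
                             tab, seed = as.integer((as.numeric(seed) + 7 * i) %% 2147483647))
    }
  }
  out <- list()
  for (tp in unique(tp_of)) {
    sel <- which(tp_of == tp)
    m <- subs[[sel[1]]]
    if (length(sel) > 1)
      for (j in sel[-1]) m <- merge_matched(m, subs[[j]], label = tp)
    else m <- fragment_set(m, tp, attr(m, "provenance"))
    out[[tp]] <- m
  }
  out
}
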