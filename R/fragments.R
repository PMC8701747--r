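#' @importFrom data.table data.table as.data.table fread fwrite setattr := .N
#' @importFrom stats rnorm runif rmultinom setNames sd cor dnorm complete.cases
#' @importFrom utils head tail
NULL

# Internal coordinates are 0-based, half-open everywhere (BED native).
# Midpoint convention: start + floor(length / 2).

#' Construct a FragmentSet
#'
#' A `FragmentSet` is a labeled collection of mapped paired-end MNase-seq
#' fragment intervals for one sample (time point x replicate). Coordinates
#' are 0-based half-open; the midpoint of a fragment is
#' `start + floor(length/2)`.
#'
#' @param fragments data.frame/data.table with columns `chrom`, `start`,
#'   `end` (0-based half-open). `length`, `midpoint` are recomputed.
#' @param label sample label, e.g. `"t20.rep1"`; must be nonempty.
#' @param provenance character vector describing source and filters applied.
#' @return An object of class `FragmentSet`: a data.table with columns
#'   `chrom`, `start`, `end`, `length`, `midpoint` (plus any extra columns
#'   such as `source`), carrying `label` and `provenance` attributes.
#' @export
fragment_set <- function(fragments, label, provenance = character()) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("'label' must be a single nonempty string")
  ft <- data.table::copy(as.data.table(fragments))
  if (nrow(ft) == 0L) {
    ft <- data.table(chrom = character(), start = integer(), end = integer())
  }
  for (col in c("chrom", "start", "end"))
    if (!col %in% names(ft)) stop("fragments must have column '", col, "'")
  ft[, `:=`(start = as.integer(start), end = as.integer(end))]
  if (nrow(ft) && any(ft$end <= ft$start))
    stop("all fragments must satisfy end > start")
  ft[, length := end - start]
  ft[, midpoint := start + length %/% 2L]
  setattr(ft, "label", label)
  setattr(ft, "provenance", provenance)
  setattr(ft, "class", c("FragmentSet", setdiff(class(ft), "FragmentSet")))
  ft
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet '%s': %d fragments", fs_label(x), nrow(x)))
  if (nrow(x))
    cat(sprintf(" on %d chromosome(s); sizes %d-%d bp",
                length(unique(x$chrom)), min(x$length), max(x$length)))
  cat("\n")
  for (p in attr(x, "provenance")) cat("  - ", p, "\n", sep = "")
  invisible(x)
}

#' @rdname fragment_set
#' @param fs a `FragmentSet`.
#' @export
fs_label <- function(fs) attr(fs, "label")

fs_annotate <- function(fs, label = fs_label(fs), note = NULL) {
  prov <- c(attr(fs, "provenance"), note)
  out <- data.table::copy(fs)
  setattr(out, "label", label)
  setattr(out, "provenance", prov)
  out
}

#' Read mapped fragments from BED3, BEDPE or paired-end BAM
#'
#' One record is produced per sequenced fragment. For BAM input, a fragment
#' is the outer span of a properly paired read pair, counted once (taken
#' from the forward-strand mate, so each pair yields exactly one record).
#' BAM support requires the Rsamtools package.
#'
#' @param path path to the input file.
#' @param format one of `"bed"`, `"bedpe"`, `"bam"`. Defaults from the file
#'   extension.
#' @param label sample label; defaults to the file name.
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, format = c("auto", "bed", "bedpe", "bam"),
                           label = basename(path)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", bedpe = "bedpe", bam = "bam",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  prov <- paste0("read from ", path, " (", format, ")")
  if (format == "bam") return(read_fragments_bam(path, label, prov))
  if (file.size(path) == 0L)
    return(fragment_set(NULL, label, prov))
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  if (format == "bed") {
    if (ncol(dt) < 3L) stop("BED input needs >= 3 columns")
    bad <- which(is.na(dt[[2]]) | is.na(dt[[3]]))
    if (length(bad))
      stop("malformed BED line(s): ", paste(head(bad, 5), collapse = ", "))
    frags <- data.table(chrom = as.character(dt[[1]]),
                        start = as.integer(dt[[2]]), end = as.integer(dt[[3]]))
  } else {
    if (ncol(dt) < 6L) stop("BEDPE input needs >= 6 columns")
    bad <- which(is.na(dt[[2]]) | is.na(dt[[3]]) | is.na(dt[[5]]) | is.na(dt[[6]]))
    if (length(bad))
      stop("malformed BEDPE line(s): ", paste(head(bad, 5), collapse = ", "))
    if (any(as.character(dt[[1]]) != as.character(dt[[4]])))
      stop("BEDPE mates on different chromosomes are not supported")
    frags <- data.table(chrom = as.character(dt[[1]]),
                        start = pmin(as.integer(dt[[2]]), as.integer(dt[[5]])),
                        end   = pmax(as.integer(dt[[3]]), as.integer(dt[[6]])))
  }
  fragment_set(frags, label, prov)
}

read_fragments_bam <- function(path, label, prov) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM requires the Rsamtools package")
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isMinusStrand = FALSE,
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("rname", "pos", "isize"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- !is.na(res$isize) & res$isize > 0L
  nskip <- sum(!keep)
  if (nskip) message(nskip, " forward-strand records without a positive ",
                     "template length skipped")
  frags <- data.table(chrom = as.character(res$rname[keep]),
                      start = res$pos[keep] - 1L,
                      end = res$pos[keep] - 1L + res$isize[keep])
  fragment_set(frags, label, c(prov, "proper pairs, forward mate only"))
}

#' Write fragments as BED3
#'
#' @param fs a `FragmentSet`.
#' @param path output path; tab-separated, 0-based half-open, one fragment
#'   per line.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fs, path) {
  fwrite(fs[, list(chrom, start, end)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# rDNA locus cited 1-based inclusive -> 0-based half-open at the boundary.
SACCER3_EXCLUSIONS <- data.frame(
  chrom = c("chrM", "chrXII"),
  start = c(0L, 451574L),
  end   = c(.Machine$integer.max, 489469L))

#' Remove fragments in excluded regions (chrM, rDNA)
#'
#' Drops fragments whose midpoint falls on mitochondrial DNA or within the
#' rDNA repeat locus (sacCer3 chrXII:451,575-489,469, converted to 0-based
#' half-open). Exclusion is by fragment midpoint, matching the
#' midpoint-based downstream scoring.
#'
#' @param fs a `FragmentSet`.
#' @param genome `"sacCer3"` for the built-in exclusion list, or `NULL` when
#'   supplying `exclude`.
#' @param exclude optional data.frame of user exclusion intervals with
#'   columns `chrom`, `start`, `end` (0-based half-open).
#' @return Filtered `FragmentSet`.
#' @export
apply_exclusions <- function(fs, genome = "sacCer3", exclude = NULL) {
  if (is.null(exclude)) {
    if (is.null(genome) || !identical(genome, "sacCer3"))
      stop("unknown genome '", genome,
           "': supply an exclusion table via 'exclude'")
    exclude <- SACCER3_EXCLUSIONS
  }
  drop <- rep(FALSE, nrow(fs))
  for (i in seq_len(nrow(exclude))) {
    drop <- drop | (fs$chrom == exclude$chrom[i] &
                      fs$midpoint >= exclude$start[i] &
                      fs$midpoint < exclude$end[i])
  }
  out <- fs[!drop]
  fragment_set(out, fs_label(fs),
               c(attr(fs, "provenance"),
                 sprintf("excluded %d fragments in %d region(s)",
                         sum(drop), nrow(exclude))))
}

#' Build a fragment midpoint-by-size occupancy matrix (V-plot)
#'
#' The chromatin occupancy profile of a region: a counts matrix indexed by
#' fragment size (rows, default 20-250 bp) and fragment-midpoint position
#' (columns). Fragments whose midpoint lies outside the region, or whose
#' size is out of range, are excluded.
#'
#' @param fs a `FragmentSet`.
#' @param chrom chromosome name.
#' @param start,end region bounds, 0-based half-open.
#' @param size_range inclusive fragment-size range, default `c(20, 250)`.
#' @return A `VPlotMatrix`: integer matrix with `dimnames` giving sizes and
#'   positions, plus `region` and `size_range` attributes.
#' @export
build_vplot <- function(fs, chrom, start, end, size_range = c(20L, 250L)) {
  if (end <= start) stop("inverted region: end must exceed start")
  sizes <- size_range[1]:size_range[2]
  positions <- start:(end - 1L)
  keep <- fs$chrom == chrom & fs$midpoint >= start & fs$midpoint < end &
    fs$length >= size_range[1] & fs$length <= size_range[2]
  sub <- fs[which(keep)]
  m <- matrix(0L, nrow = length(sizes), ncol = length(positions),
              dimnames = list(size = sizes, position = positions))
  if (nrow(sub)) {
    idx <- data.table(i = sub$length - size_range[1] + 1L,
                      j = sub$midpoint - start + 1L)
    cnt <- idx[, .N, by = list(i, j)]
    m[cbind(cnt$i, cnt$j)] <- cnt$N
  }
  structure(m, region = list(chrom = chrom, start = start, end = end),
            size_range = size_range, class = c("VPlotMatrix", "matrix", "array"))
}

#' Per-base midpoint counts for one chromosome
#'
#' @param fs a `FragmentSet`.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param size_range optional inclusive size filter, e.g. `c(20, 119)`.
#' @return Numeric vector of length `chrom_length`; element `p + 1` counts
#'   fragment midpoints at 0-based position `p`.
#' @export
midpoint_counts <- function(fs, chrom, chrom_length, size_range = NULL) {
  keep <- fs$chrom == chrom & fs$midpoint >= 0L & fs$midpoint < chrom_length
  if (!is.null(size_range))
    keep <- keep & fs$length >= size_range[1] & fs$length <= size_range[2]
  tabulate(fs$midpoint[keep] + 1L, nbins = chrom_length)
}
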