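# Small builders shared across test files.

# FragmentSet from parallel vectors of midpoints and lengths on one chromosome
fs_from_mids <- function(mids, lens, chrom = "chrI", label = "fix") {
  start <- as.integer(mids - lens %/% 2L)
  fragment_set(data.frame(chrom = chrom, start = start,
                          end = start + as.integer(lens)), label)
}

# n fragments of a single size with given per-size composition:
# sizes is a named vector size -> count
fs_with_size_counts <- function(size_counts, label, chrom = "chrI") {
  lens <- rep(as.integer(names(size_counts)), size_counts)
  mids <- seq(500L, by = 7L, length.out = length(lens))
  fs_from_mids(mids, lens, chrom = chrom, label = label)
}

# plain nucleosome-array layout: no origins, no Abf1 sites
array_layout <- function(chrom_len = 60000L, fuzziness_sd = 10,
                         background_rate = 0, seed = 1L, ...) {
  build_layout(c(chrT = as.integer(chrom_len)),
               n_origins = c(g1g2 = 0L, g1only = 0L),
               fuzziness_sd = fuzziness_sd, n_abf1 = 0L,
               background_rate = background_rate, seed = seed, ...)
}

g1_timepoint <- function() list(label = "alpha", minutes = 0, front = numeric(0))

# brute-force nucleosome score at one 0-based position (independent oracle)
naive_score <- function(fs, kernel, chrom, pos) {
  ksz <- as.integer(rownames(kernel$weights))
  offs <- as.integer(colnames(kernel$weights))
  tot <- 0
  for (r in seq_len(nrow(fs))) {
    if (fs$chrom[r] != chrom) next
    d <- fs$midpoint[r] - pos
    s <- fs$length[r]
    if (d >= min(offs) && d <= max(offs) && s >= min(ksz) && s <= max(ksz))
      tot <- tot + kernel$weights[as.character(s), as.character(d)]
  }
  tot
}
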