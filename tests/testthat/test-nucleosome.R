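test_that("dyad pileup counts midpoints at their offsets, totals oracle-checked", {
  fs <- fs_from_mids(1000, 166)
  p <- aggregate_reference_pileup(fs, data.frame(chrom = "chrI", pos = 1000),
                                  halfwidth = 100)
  expect_equal(sum(p), 1)
  expect_equal(p["166", "0"], 1L)

  set.seed(23)
  dyads <- data.frame(chrom = "chrI", pos = seq(2000, 8000, by = 300))
  mids <- sample.int(10000, 2000, replace = TRUE)
  lens <- sample(20:250, 2000, replace = TRUE)
  fs2 <- fs_from_mids(pmax(mids, 200), lens)
  p2 <- aggregate_reference_pileup(fs2, dyads, halfwidth = 100)
  brute <- 0L
  for (d in dyads$pos) brute <- brute + sum(abs(fs2$midpoint - d) <= 100)
  expect_equal(sum(p2), brute)
  # symmetric generator: mean midpoint offset near 0
  offs <- as.integer(colnames(p2))
  expect_lt(abs(sum(offs * colSums(p2)) / sum(p2)), 5)
})

test_that("kernel variances shrink the pileup marginals by 1/16 and 1/4", {
  sizes <- 20:250; offs <- -100:100
  pile <- matrix(0, length(sizes), length(offs),
                 dimnames = list(sizes, offs))
  # two-point marginals with known variance: sizes 146/186 (var 400),
  # offsets -40/+40 (var 1600)
  pile[c("146", "186"), c("-40", "40")] <- 1
  k <- fit_kernel(pile)
  expect_equal(k$params$marginal_var_size, 400)
  expect_equal(k$params$sigma2_size, 25)
  expect_equal(k$params$marginal_var_pos, 1600)
  expect_equal(k$params$sigma2_pos, 400)
  expect_equal(sum(k$weights), 1)
  # separable product of two 1D Gaussians
  expect_equal(k$weights, outer(rowSums(k$weights), colSums(k$weights)),
               tolerance = 1e-12, ignore_attr = TRUE)
  degen <- matrix(0, length(sizes), length(offs),
                  dimnames = list(sizes, offs))
  degen["166", "0"] <- 5
  expect_error(fit_kernel(degen), "degenerate")
  expect_error(fit_kernel(pile * 0), "empty")
})

test_that("cross-correlation scores match a naive double loop and are linear", {
  lay <- array_layout(chrom_len = 20000L, background_rate = 1e-3, seed = 3)
  fs <- simulate_sample(lay, g1_timepoint(), 4000, seed = 8)
  pile <- aggregate_reference_pileup(fs, lay$dyads[, c("chrom", "pos")])
  k <- fit_kernel(pile)
  vp <- build_vplot(fs, "chrT", 2000L, 6000L)
  tr <- score_nucleosomes(vp, k)
  expect_length(tr, 4000)
  set.seed(41)
  for (pos in sample(2300:5700, 25)) {
    expect_equal(tr[pos - 2000 + 1], naive_score(fs, k, "chrT", pos),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # empty region scores zero
  expect_true(all(score_nucleosomes(build_vplot(fs, "chrT", 2000L, 2100L) * 0L,
                                    k) == 0))
  # a single fragment at the kernel's modal size peaks exactly at its midpoint
  one <- fs_from_mids(3000, round(k$params$mu_size), chrom = "chrT")
  tr1 <- score_nucleosomes(build_vplot(one, "chrT", 2500L, 3500L), k)
  expect_equal(which.max(tr1), 3000 - 2500 + 1)
  # linearity: score of a merged set = sum of component scores
  a <- fs_from_mids(c(2900, 3100), c(150, 170), chrom = "chrT")
  b <- fs_from_mids(c(3000, 3050), c(166, 140), chrom = "chrT")
  m <- merge_matched(fragment_set(a, "x.rep1"), fragment_set(b, "x.rep2"))
  sa <- score_nucleosomes(build_vplot(a, "chrT", 2500L, 3500L), k)
  sb <- score_nucleosomes(build_vplot(b, "chrT", 2500L, 3500L), k)
  sm <- score_nucleosomes(build_vplot(m, "chrT", 2500L, 3500L), k)
  expect_equal(as.numeric(sm), as.numeric(sa) + as.numeric(sb),
               tolerance = 1e-12)
  # genome-wide fast path agrees with the windowed scorer
  trg <- nucleosome_track(fs, k, "chrT", 20000L)
  expect_equal(as.numeric(trg[2200:5800]), as.numeric(tr[200:3800]),
               tolerance = 1e-12)
})

test_that("copy-number ratios follow windowed RPKM arithmetic", {
  # ref: 100 of 10000 in-window; t: 400 of 20000 -> ratio 2
  mk <- function(n_in, n_out) {
    mids <- c(round(seq(5000 - 450, 5000 + 450, length.out = n_in)),
              round(seq(20000, 80000, length.out = n_out)))
    fs_from_mids(mids, rep(100L, n_in + n_out), chrom = "chrC")
  }
  ref <- mk(100, 9900); tt <- mk(400, 19600)
  r <- compute_copy_number(tt, ref, "chrC", 100000L, positions = 5000L)
  expect_equal(as.numeric(r), 2.0, tolerance = 1e-12)
  # identity at the reference sample
  self <- compute_copy_number(ref, ref, "chrC", 100000L,
                              positions = c(5000L, 50000L))
  expect_equal(as.numeric(self), c(1, 1))
  # empty reference window is flagged missing, never infinite
  r2 <- compute_copy_number(tt, ref, "chrC", 100000L, positions = 95000L)
  expect_true(is.na(as.numeric(r2)))
})

test_that("copy-number normalization rescales and propagates missingness", {
  tr <- structure(c(1, 2, 4, 8), kind = "nucleosome")
  expect_equal(as.numeric(normalize_track(tr, 1)), c(1, 2, 4, 8))
  expect_equal(as.numeric(normalize_track(tr, 2)), c(0.5, 1, 2, 4))
  out <- normalize_track(tr, c(1, 2, NA, 0))
  expect_equal(as.numeric(out), c(1, 1, NA, NA))
  expect_error(normalize_track(tr, c(1, 2)), "length mismatch")
})
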