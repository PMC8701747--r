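test_that("layout dyad count follows spacing arithmetic and NFRs are dyad-free", {
  lay <- build_layout(c(chrA = 100000L), n_origins = c(g1g2 = 1L, g1only = 1L),
                      nucleosome_spacing = 165L, n_abf1 = 0L, seed = 2)
  # independent arithmetic: array positions minus those in origin
  # exclusion zones, plus one -1 and one +1 dyad per origin
  pos <- seq(max(round(165 / 2), 130), 100000 - 200, by = 165)
  excl <- max(95, max(c(160, 126)) + 25) + 60
  for (a in lay$origins$acs) pos <- pos[abs(pos - a) > excl]
  expect_equal(sum(lay$dyads$role == "array"), length(pos))
  expect_equal(sum(lay$dyads$role != "array"), 2L * nrow(lay$origins))
  # no dyad strictly inside any NFR (between the -1 and +1 dyads)
  for (i in seq_len(nrow(lay$origins))) {
    o <- lay$origins[i, ]
    flank <- lay$dyads[lay$dyads$origin %in% o$name, ]
    inner <- lay$dyads$chrom == o$chrom &
      lay$dyads$pos > min(flank$pos) & lay$dyads$pos < max(flank$pos)
    expect_equal(sum(inner), 0L)
  }
})

test_that("zero-origin configs give a pure array and identical layouts per seed", {
  lay <- array_layout()
  expect_null(lay$origins)
  expect_true(all(lay$dyads$role == "array"))
  expect_identical(array_layout(seed = 42), array_layout(seed = 42))
  lay2 <- build_layout(c(chrA = 90000L), n_origins = c(g1g2 = 2L, g1only = 1L),
                       seed = 9)
  expect_identical(lay2,
                   build_layout(c(chrA = 90000L),
                                n_origins = c(g1g2 = 2L, g1only = 1L),
                                seed = 9))
})

test_that("layouts with origins packed closer than the window span are rejected", {
  expect_error(build_layout(c(chrA = 40000L),
                            n_origins = c(g1g2 = 8L, g1only = 0L),
                            origin_margin = 1000L, min_origin_gap = 8000L),
               "min_origin_gap")
})

test_that("zero fuzziness puts every nucleosomal midpoint on its dyad", {
  lay <- array_layout(fuzziness_sd = 0, background_rate = 0)
  fs <- simulate_sample(lay, g1_timepoint(), 5000, seed = 4)
  expect_true(all(fs$source == "nucleosome"))
  expect_true(all(fs$midpoint %in% lay$dyads$pos))
  # nucleosomal sizes stay in the truncation range with the planted mode
  expect_gte(min(fs$length), 120)
  expect_lte(max(fs$length), 250)
  expect_equal(as.integer(names(which.max(table(fs$length)))), 166L,
               tolerance = 2)
})

test_that("simulated samples are deterministic and account for every fragment", {
  lay <- build_layout(c(chrA = 80000L), n_origins = c(g1g2 = 1L, g1only = 1L),
                      seed = 6)
  tp <- default_timepoints(lay, minutes = c(0, 30))[[2]]
  a <- simulate_sample(lay, tp, 20000, seed = 13)
  b <- simulate_sample(lay, tp, 20000, seed = 13)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(sum(attr(a, "source_counts")), 20000)
  expect_equal(unname(attr(a, "source_counts")),
               unname(c(table(factor(a$source, levels = c(
                 "nucleosome", "footprint", "abf1", "background"))))))
})

test_that("configured footprint fraction is recovered within binomial error", {
  lay <- build_layout(c(chrA = 100000L), n_origins = c(g1g2 = 1L, g1only = 0L),
                      n_abf1 = 0L, background_rate = 0, seed = 8)
  tp <- g1_timepoint()
  # rescale the footprint weight so its share of total weight is exactly 0.10
  w_fp <- oricycle:::footprint_occ_at(lay, 0)
  w_nuc <- nrow(lay$dyads)
  lay$params$footprint_weight <-
    lay$params$footprint_weight * (w_nuc / 9) / w_fp
  fs <- simulate_sample(lay, list(label = "x", minutes = 0,
                                  front = c(ARSsim001 = 0)), 10000, seed = 3)
  n_small <- sum(fs$length < 120)
  expect_lt(abs(n_small - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
})

test_that("replicated regions carry twice the fragment density", {
  lay <- build_layout(c(chrA = 120000L), n_origins = c(g1g2 = 1L, g1only = 0L),
                      n_abf1 = 0L, background_rate = 0, seed = 5)
  acs <- lay$origins$acs
  tp <- list(label = "s", minutes = 30, front = c(ARSsim001 = 20000))
  fs <- simulate_sample(lay, tp, 2e5, seed = 21)
  # equal-width windows of the uniform array, inside vs outside the front
  n_in <- sum(fs$midpoint >= acs + 2000 & fs$midpoint < acs + 12000)
  n_out <- sum(fs$midpoint >= acs + 26000 & fs$midpoint < acs + 36000)
  ratio <- n_in / n_out
  se <- ratio * sqrt(1 / n_in + 1 / n_out)
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("time courses produce one labeled set per time point and replicate", {
  lay <- build_layout(c(chrA = 80000L), n_origins = c(g1g2 = 1L, g1only = 1L),
                      seed = 7)
  tps <- default_timepoints(lay)
  expect_length(tps, 16)
  sim <- simulate_timecourse(lay, tps, depth = 300, replicates = 2, seed = 1)
  expect_length(sim$fragmentsets, 32)
  expect_false(anyDuplicated(names(sim$fragmentsets)) > 0)
  expect_true(all(rowSums(sim$truth$source_counts) == 300))
  # per-origin fronts never shrink over time
  fronts <- sapply(tps, `[[`, "front")
  expect_true(all(apply(fronts, 1, function(x) all(diff(x) >= 0))))

  z <- simulate_sample(lay, tps[[1]], 0, seed = 1)
  expect_equal(nrow(z), 0L)
  expect_error(simulate_timecourse(lay, tps[c(1, 1)], 10),
               "duplicate")
})
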