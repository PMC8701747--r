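test_that("aggregation orients minus-strand origins and averages linearly", {
  L <- 10000L
  base <- dnorm(seq(-500, 500), 160, 40)  # asymmetric bump downstream
  plus_tr <- numeric(L); plus_tr[(3000 - 500):(3000 + 500) + 1] <- base
  minus_tr <- numeric(L); minus_tr[(7000 - 500):(7000 + 500) + 1] <- rev(base)
  tracks <- list(chrA = plus_tr + minus_tr)
  origins <- data.frame(name = c("p", "m"), chrom = "chrA",
                        acs = c(3000L, 7000L), strand = c("+", "-"))
  agg <- orient_and_aggregate(tracks, origins, halfspan = 500L)
  one <- orient_and_aggregate(tracks, origins[1, ], halfspan = 500L)
  expect_equal(as.numeric(agg), as.numeric(one), tolerance = 1e-12)
  expect_equal(attr(agg, "n"), 2L)
  # identity for a single origin
  expect_equal(as.numeric(one), base, tolerance = 1e-12)
  # linearity: pooled aggregate = weighted mean of subset aggregates
  o3 <- data.frame(name = c("p", "p2", "m"), chrom = "chrA",
                   acs = c(3000L, 3000L, 7000L),
                   strand = c("+", "+", "-"))
  a12 <- orient_and_aggregate(tracks, o3[1:2, ], 500L)
  a3 <- orient_and_aggregate(tracks, o3[3, , drop = FALSE], 500L)
  all3 <- orient_and_aggregate(tracks, o3, 500L)
  expect_equal(as.numeric(all3), (2 * as.numeric(a12) + as.numeric(a3)) / 3,
               tolerance = 1e-12)
  # origins near chromosome ends are skipped
  oend <- rbind(origins, data.frame(name = "e", chrom = "chrA", acs = 100L,
                                    strand = "+"))
  expect_equal(attr(orient_and_aggregate(tracks, oend, 500L), "n"), 2L)
  expect_error(orient_and_aggregate(tracks, oend[3, , drop = FALSE], 500L),
               "no origin window")
})

test_that("dyad calls locate the -1/+1 maxima with ties broken toward the ACS", {
  offs <- -600:600
  prof <- setNames(numeric(length(offs)), offs)
  prof[as.character(c(-80, 150))] <- c(3, 5)
  dc <- call_dyads(prof)
  expect_equal(dc$minus_one, -80)
  expect_equal(dc$plus_one, 150)
  expect_equal(dc$nfr_width, 230)
  expect_false(dc$low_confidence)
  # mirroring the profile (strand flip) mirrors nothing after orientation:
  # an oriented profile of the minus strand is the reverse of the plus track
  mirror <- setNames(rev(as.numeric(prof)), offs)
  dcm <- call_dyads(mirror)
  expect_equal(dcm$minus_one, -150)
  expect_equal(dcm$plus_one, 80)
  expect_equal(dcm$nfr_width, dc$nfr_width)
  # ties break toward the ACS on both sides
  tied <- setNames(numeric(length(offs)), offs)
  tied[as.character(c(-300, -120, 120, 300))] <- 7
  dct <- call_dyads(tied)
  expect_equal(dct$minus_one, -120)
  expect_equal(dct$plus_one, 120)
  flat <- setNames(rep(1, length(offs)), offs)
  expect_true(call_dyads(flat)$low_confidence)
})

test_that("footprint peak averages fix the peak on the time-mean profile", {
  offs <- -200:200
  shape <- dnorm(offs, 0, 30)
  profs <- cbind(t1 = shape * 1, t2 = shape * 3, t3 = shape * 2)
  rownames(profs) <- offs
  pa <- footprint_peak_average(profs)
  expect_equal(attr(pa, "peak_offset"), 0L)
  expect_equal(unname(which.max(pa)), 2L)
  const <- cbind(t1 = rep(2, 401), t2 = rep(5, 401))
  rownames(const) <- offs
  expect_equal(as.numeric(footprint_peak_average(const)), c(2, 5))
  # halfwidth 0 reads the peak base exactly
  expect_equal(as.numeric(footprint_peak_average(profs, halfwidth = 0L)),
               as.numeric(profs["0", ]))
})

test_that("efficiency correlation is rank-based and robust to the log transform", {
  set.seed(44)
  n <- 60
  eff <- runif(n)
  dens <- cbind(t1 = exp(2 * eff), t2 = runif(n))  # monotone, then unrelated
  rownames(dens) <- paste0("o", 1:n)
  out <- efficiency_correlation(dens, eff)
  expect_equal(out$rho[1], 1)
  expect_equal(out$n, c(n, n))
  # log2 transform is rank-preserving for positive densities
  raw_rho <- cor(dens[, 2], eff, method = "spearman")
  expect_equal(out$rho[2], raw_rho, tolerance = 1e-12)
  # missing efficiencies drop pairwise; zero variance flags NA
  eff2 <- eff; eff2[1:10] <- NA
  out2 <- efficiency_correlation(dens, eff2)
  expect_equal(out2$n, c(50L, 50L))
  outz <- efficiency_correlation(cbind(t1 = rep(2, n)), eff)
  expect_true(is.na(outz$rho))
})

test_that("origin tables round-trip through TSV with validation", {
  o <- data.frame(name = c("ARS1", "ARS2"), chrom = "chrIV",
                  acs = c(1000L, 9000L), strand = c("+", "-"),
                  class = c("G1&G2", "G1only"), efficiency = c(0.9, 0.2))
  p <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(o, p, sep = "\t")
  back <- read_origins(p)
  expect_equal(as.data.frame(back), o)
  bad <- o; bad$strand <- c("+", "x")
  data.table::fwrite(bad, p, sep = "\t")
  expect_error(read_origins(p), "strand")
})
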