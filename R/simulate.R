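#' Build a synthetic genome layout with planted chromatin features
#'
#' Constructs the ground truth for the simulator: chromosomes carrying a
#' regularly spaced nucleosome array, replication origins anchored at an
#' ACS with a nucleosome-free region (NFR) flanked by -1/+1 nucleosomes,
#' and Abf1-like small-factor binding sites. Origin activation efficiency
#' and small-fragment (footprint) occupancy are drawn from a Gaussian
#' copula so their population Spearman correlation equals
#' `efficiency_rho`.
#'
#' Defaults emulate the measured architecture of budding-yeast origins:
#' nucleosomal fragments mode 166 bp, NFR dyad-to-dyad spans near 255 bp
#' ("G1&G2" class, the more efficient origins with a persistent ORC
#' footprint) and 221 bp ("G1only" class), footprint occupancy peaking in
#' late G1/early S, and a transient +1-nucleosome shift away from the ACS
#' at the G1/S transition for the "G1&G2" class.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_origins named vector `c(g1g2 = ..., g1only = ...)`: origin
#'   count per footprint class.
#' @param nucleosome_spacing dyad-to-dyad spacing of the background array (bp).
#' @param fuzziness_sd positional SD of nucleosomal fragment midpoints
#'   around their dyad (bp).
#' @param minus_one_offset distance of the -1 dyad upstream of the ACS (bp).
#' @param plus_one_offset named vector: baseline +1 dyad distance downstream
#'   of the ACS per class (bp).
#' @param plus_one_shift `c(amp, peak, width)`: transient extra +1
#'   displacement (bp) for "G1&G2" origins, Gaussian in time (min).
#' @param flank_occupancy relative occupancy of the -1/+1 dyads; origin
#'   flanks are the well-positioned, strongly occupied nucleosomes, which
#'   keeps the innermost-maximum dyad call identifiable over the distal
#'   array.
#' @param footprint_peak_time,footprint_period timing (min) of the cyclic
#'   footprint-occupancy profile: peak in late G1/early S, one cell cycle
#'   per period.
#' @param synchrony_decay e-folding time (min) of the cyclic amplitude,
#'   modeling gradual desynchronization of the culture after release.
#' @param footprint_base floor of the cyclic occupancy profile (fraction of
#'   its peak). The floor carries an origin-specific scale that is not
#'   coupled to efficiency, so the efficiency-occupancy correlation is
#'   specific to the cyclic late-G1/early-S component; set to 0 for a
#'   fully coupled profile.
#' @param class_amplitude multiplicative footprint amplitude per class
#'   ("G1only" origins carry a dampened footprint).
#' @param efficiency_rho target population Spearman correlation between
#'   origin efficiency and footprint occupancy scale (within class).
#' @param fire_threshold origins with efficiency at or above this fire
#'   (finite activation time); below, they are passively replicated
#'   (activation time `Inf`).
#' @param activation_window `c(earliest, latest)` activation times (min);
#'   efficiency 1 fires at the earliest, efficiency at threshold at the
#'   latest.
#' @param n_abf1 number of Abf1-like sites per chromosome.
#' @param abf1_weight,footprint_weight,nucleosome_weight relative sampling
#'   weights of one Abf1 site, one origin footprint at its peak with unit
#'   occupancy scale, and one nucleosome dyad.
#' @param background_rate background fragments per bp per unit nucleosome
#'   weight.
#' @param fork_disruption if `TRUE`, nucleosomes within `fork_window` bp
#'   behind an active replication fork get `fork_fuzz_add` bp of extra
#'   positional fuzziness (replication-coupled disorganization).
#' @param fork_window,fork_fuzz_add width (bp) and magnitude of the
#'   disrupted band behind the fork. The default width is the distance a
#'   fork travels during a ~10 min chromatin-restoration lag at 1000
#'   bp/min, so disorganization persists while nucleosomes reassemble in
#'   the fork's wake.
#' @param origin_margin minimum distance of an ACS from a chromosome end (bp).
#' @param min_origin_gap reject layouts whose origins are closer than this (bp).
#' @param seed integer seed; layouts are deterministic given config + seed.
#' @return A `GenomeLayout` list: `chrom_lengths`, `dyads`, `origins`,
#'   `abf1_sites`, and the generating parameters.
#' @export
build_layout <- function(chrom_lengths = c(chrSim = 200000L),
                         n_origins = c(g1g2 = 2L, g1only = 2L),
                         nucleosome_spacing = 165L,
                         fuzziness_sd = 10,
                         minus_one_offset = 95L,
                         plus_one_offset = c(g1g2 = 160L, g1only = 126L),
                         flank_occupancy = 1.25,
                         plus_one_shift = c(amp = 25, peak = 10, width = 15),
                         footprint_peak_time = 20,
                         footprint_period = 70,
                         footprint_base = 0.2,
                         synchrony_decay = 60,
                         class_amplitude = c(g1g2 = 1, g1only = 0.3),
                         efficiency_rho = 0.6,
                         fire_threshold = 0.5,
                         activation_window = c(15, 40),
                         n_abf1 = 4L,
                         abf1_weight = 6,
                         footprint_weight = 4,
                         nucleosome_weight = 1,
                         background_rate = 2e-4,
                         fork_disruption = TRUE,
                         fork_window = 10000L,
                         fork_fuzz_add = 30,
                         origin_margin = 16000L,
                         min_origin_gap = 2000L,
                         seed = 1L) {
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            fuzziness_sd >= 0, nucleosome_spacing > 0)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chrSim", seq_along(chrom_lengths))
  set.seed(seed)

  n_tot <- sum(n_origins)
  origins <- NULL
  if (n_tot > 0) {
    # distribute origins across chromosomes proportionally to length,
    # evenly spaced within [margin, L - margin]
    per_chrom <- diff(round(cumsum(c(0, chrom_lengths / sum(chrom_lengths))) * n_tot))
    acs <- integer(); ochrom <- character()
    for (ci in seq_along(chrom_lengths)) {
      k <- per_chrom[ci]
      if (k == 0) next
      L <- chrom_lengths[ci]
      lo <- origin_margin; hi <- L - origin_margin
      if (hi <= lo) stop("chromosome ", names(chrom_lengths)[ci],
                         " too short for origin_margin ", origin_margin)
      pos <- round(lo + (seq_len(k) - 0.5) / k * (hi - lo))
      if (k > 1 && min(diff(pos)) < min_origin_gap)
        stop("origins closer than min_origin_gap (", min_origin_gap,
             " bp); reduce origin count or enlarge the genome")
      acs <- c(acs, pos); ochrom <- c(ochrom, rep(names(chrom_lengths)[ci], k))
    }
    cls <- rep(names(n_origins), n_origins)
    # shuffle class assignment over placed positions so classes interleave
    cls <- sample(cls)
    # Gaussian copula: Spearman rho_s of a bivariate normal with Pearson r
    # is (6/pi) asin(r/2); invert to hit the target rho_s
    r <- 2 * sin(pi * efficiency_rho / 6)
    z1 <- rnorm(n_tot)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n_tot)
    u <- stats::pnorm(z1)
    eff <- ifelse(cls == "g1g2", 0.45 + 0.5 * u, 0.05 + 0.5 * u)
    occ_scale <- exp(0.35 * z2)
    # the floor of the cyclic occupancy gets its own, uncoupled scale, so
    # efficiency is coupled to the late-G1/early-S occupancy component only
    base_scale <- exp(0.35 * rnorm(n_tot))
    act <- ifelse(eff >= fire_threshold,
                  activation_window[1] + (activation_window[2] - activation_window[1]) *
                    (1 - eff) / max(1e-9, 1 - fire_threshold),
                  Inf)
    origins <- data.table(
      name = sprintf("ARSsim%03d", seq_len(n_tot)),
      chrom = ochrom, acs = as.integer(acs),
      strand = sample(c("+", "-"), n_tot, replace = TRUE),
      class = ifelse(cls == "g1g2", "G1&G2", "G1only"),
      efficiency = eff, occ_scale = occ_scale, base_scale = base_scale,
      activation_time = act)
  }

  abf1 <- NULL
  if (n_abf1 > 0) {
    ab <- list()
    for (ci in seq_along(chrom_lengths)) {
      cn <- names(chrom_lengths)[ci]; L <- chrom_lengths[ci]
      cand <- round(seq(origin_margin / 2, L - origin_margin / 2,
                        length.out = n_abf1 + 2))[2:(n_abf1 + 1)]
      # keep Abf1 sites away from origins so calibration is independent
      if (!is.null(origins)) {
        oo <- origins[origins$chrom == cn, ]
        for (i in seq_len(nrow(oo))) {
          shift_away <- abs(cand - oo$acs[i]) < 1500
          cand[shift_away] <- cand[shift_away] + 2500L
        }
      }
      ab[[cn]] <- data.table(chrom = cn, pos = as.integer(cand))
    }
    abf1 <- data.table::rbindlist(ab)
  }

  # nucleosome array: exclude dyads falling inside any origin NFR zone or
  # the nucleosome-depleted region around an Abf1 site (Abf1 is an
  # NFR-forming general regulatory factor)
  dyads_list <- list()
  excl_r <- max(minus_one_offset, max(plus_one_offset) + plus_one_shift[["amp"]]) + 60
  for (ci in seq_along(chrom_lengths)) {
    cn <- names(chrom_lengths)[ci]; L <- chrom_lengths[ci]
    # keep dyads >= 130 bp from the ends so whole fragments fit inside
    pos <- seq(from = max(round(nucleosome_spacing / 2), 130L), to = L - 200,
               by = nucleosome_spacing)
    if (!is.null(origins)) {
      oo <- origins[origins$chrom == cn, ]
      for (i in seq_len(nrow(oo)))
        pos <- pos[abs(pos - oo$acs[i]) > excl_r]
    }
    if (!is.null(abf1)) {
      aa <- abf1[abf1$chrom == cn, ]
      for (i in seq_len(nrow(aa)))
        pos <- pos[abs(pos - aa$pos[i]) > 120]
    }
    dyads_list[[cn]] <- data.table(chrom = cn, pos = as.integer(pos),
                                   fuzziness_sd = fuzziness_sd,
                                   occupancy = 1, role = "array",
                                   origin = NA_character_)
  }
  dyads <- data.table::rbindlist(dyads_list)
  if (!is.null(origins)) {
    sgn <- ifelse(origins$strand == "+", 1L, -1L)
    p1_base <- plus_one_offset[[ "g1g2" ]] * (origins$class == "G1&G2") +
      plus_one_offset[[ "g1only" ]] * (origins$class == "G1only")
    flank <- data.table(
      chrom = rep(origins$chrom, 2),
      pos = c(origins$acs - sgn * minus_one_offset,
              origins$acs + sgn * as.integer(p1_base)),
      fuzziness_sd = fuzziness_sd, occupancy = flank_occupancy,
      role = rep(c("minus1", "plus1"), each = nrow(origins)),
      origin = rep(origins$name, 2))
    dyads <- data.table::rbindlist(list(dyads, flank))
  }

  structure(list(
    chrom_lengths = chrom_lengths, dyads = dyads, origins = origins,
    abf1_sites = abf1,
    params = list(
      nucleosome_spacing = nucleosome_spacing, fuzziness_sd = fuzziness_sd,
      minus_one_offset = minus_one_offset, plus_one_offset = plus_one_offset,
      plus_one_shift = plus_one_shift,
      footprint_peak_time = footprint_peak_time,
      footprint_period = footprint_period, footprint_base = footprint_base,
      synchrony_decay = synchrony_decay,
      class_amplitude = class_amplitude, efficiency_rho = efficiency_rho,
      nucleosome_weight = nucleosome_weight,
      footprint_weight = footprint_weight, abf1_weight = abf1_weight,
      background_rate = background_rate,
      fork_disruption = fork_disruption, fork_window = fork_window,
      fork_fuzz_add = fork_fuzz_add, seed = seed)),
    class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$chrom_lengths), "chromosome(s),",
      sum(as.numeric(x$chrom_lengths)), "bp total\n")
  cat(" ", nrow(x$dyads), "nucleosome dyads;",
      if (is.null(x$origins)) 0 else nrow(x$origins), "origins;",
      if (is.null(x$abf1_sites)) 0 else nrow(x$abf1_sites), "Abf1 sites\n")
  invisible(x)
}

#' Cell-cycle time points with per-origin replication fronts
#'
#' Builds the simulated time course: an alpha-factor arrest sample (G1,
#' copy number 1 everywhere) followed by samples every 10 min after
#' release. Replication is modeled as a deterministic bidirectional front
#' expanding from each fired origin at `fork_speed` bp/min from its
#' activation time.
#'
#' @param layout a `GenomeLayout`.
#' @param minutes numeric vector of minutes post release; 0 is the
#'   alpha-factor arrest point. Default: alpha plus every 10 min to 150.
#' @param fork_speed replication fork speed (bp/min).
#' @return List of time-point specs, each with `label`, `minutes`, and
#'   `front` (named vector: bp replicated on each side of each origin; 0
#'   outside S phase or for passive origins).
#' @export
default_timepoints <- function(layout, minutes = c(0, seq(10, 150, by = 10)),
                               fork_speed = 1000) {
  labels <- ifelse(minutes == 0, "alpha", paste0("t", minutes))
  if (anyDuplicated(labels)) stop("duplicate time-point labels")
  lapply(seq_along(minutes), function(i) {
    front <- numeric(0)
    if (!is.null(layout$origins)) {
      front <- pmax(0, fork_speed * (minutes[i] - layout$origins$activation_time))
      front[!is.finite(layout$origins$activation_time)] <- 0
      names(front) <- layout$origins$name
    }
    list(label = labels[i], minutes = minutes[i], front = front,
         fork_speed = fork_speed)
  })
}

# cyclic footprint occupancy weight for origin i at time t (min)
footprint_occ_at <- function(layout, minutes) {
  p <- layout$params
  if (is.null(layout$origins)) return(numeric(0))
  w <- (1 + cos(2 * pi * (minutes - p$footprint_peak_time) / p$footprint_period)) / 2
  # cultures desynchronize after release: the cyclic amplitude decays, so
  # the first-cycle peak dominates later cycles
  w <- 0.5 + (w - 0.5) * exp(-minutes / p$synchrony_decay)
  amp <- ifelse(layout$origins$class == "G1&G2",
                p$class_amplitude[["g1g2"]], p$class_amplitude[["g1only"]])
  p$footprint_weight * amp *
    (p$footprint_base * layout$origins$base_scale +
       (1 - p$footprint_base) * w * layout$origins$occ_scale)
}

# +1 dyad offset from the ACS (bp, T-rich orientation) at time t
plus_one_offset_at <- function(layout, minutes) {
  p <- layout$params
  base <- ifelse(layout$origins$class == "G1&G2",
                 p$plus_one_offset[["g1g2"]], p$plus_one_offset[["g1only"]])
  sh <- p$plus_one_shift
  shift <- sh[["amp"]] * exp(-((minutes - sh[["peak"]]) / sh[["width"]])^2)
  base + ifelse(layout$origins$class == "G1&G2", shift, 0)
}

# replicated intervals per chromosome at a time point (list of matrices)
replicated_intervals <- function(layout, tp) {
  out <- lapply(layout$chrom_lengths, function(L) matrix(numeric(0), ncol = 2))
  if (is.null(layout$origins) || !length(tp$front)) return(out)
  fired <- which(tp$front > 0)
  for (i in fired) {
    cn <- layout$origins$chrom[i]
    L <- layout$chrom_lengths[[cn]]
    iv <- c(max(0, layout$origins$acs[i] - tp$front[i]),
            min(L, layout$origins$acs[i] + tp$front[i]))
    out[[cn]] <- rbind(out[[cn]], iv)
  }
  # merge overlaps
  for (cn in names(out)) {
    m <- out[[cn]]
    if (nrow(m) <= 1) next
    m <- m[order(m[, 1]), , drop = FALSE]
    merged <- m[1, , drop = FALSE]
    for (k in 2:nrow(m)) {
      if (m[k, 1] <= merged[nrow(merged), 2])
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], m[k, 2])
      else merged <- rbind(merged, m[k, ])
    }
    out[[cn]] <- merged
  }
  out
}

in_intervals <- function(pos, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv)))
    hit <- hit | (pos >= iv[k, 1] & pos < iv[k, 2])
  hit
}

#' Effective nucleosome dyads at a time point
#'
#' Applies the time-dependent +1-nucleosome displacement and the
#' replication-fork fuzziness disruption to the layout's dyad table; this
#' is the positional truth downstream dyad calls are checked against.
#'
#' @param layout a `GenomeLayout`.
#' @param tp one element of [default_timepoints()].
#' @return data.table like `layout$dyads` with adjusted `pos` and
#'   `fuzziness_sd`.
#' @export
effective_dyads <- function(layout, tp) {
  d <- data.table::copy(layout$dyads)
  if (!is.null(layout$origins)) {
    p1 <- which(d$role == "plus1")
    if (length(p1)) {
      oi <- match(d$origin[p1], layout$origins$name)
      sgn <- ifelse(layout$origins$strand[oi] == "+", 1L, -1L)
      off <- plus_one_offset_at(layout, tp$minutes)[oi]
      d$pos[p1] <- as.integer(round(layout$origins$acs[oi] + sgn * off))
    }
    if (isTRUE(layout$params$fork_disruption) && any(tp$front > 0)) {
      speed <- if (!is.null(tp$fork_speed)) tp$fork_speed else 1000
      maturation <- layout$params$fork_window / speed
      fired <- which(is.finite(layout$origins$activation_time))
      # replication time of each locus: earliest arrival over fired
      # origins; converging forks terminate where the minima meet, and a
      # locus stays disrupted only during the restoration lag after its
      # own replication
      for (cn in unique(layout$origins$chrom[fired])) {
        sel <- which(d$chrom == cn)
        if (!length(sel)) next
        a <- rep(Inf, length(sel))
        for (i in fired[layout$origins$chrom[fired] == cn]) {
          a <- pmin(a, layout$origins$activation_time[i] +
                      abs(d$pos[sel] - layout$origins$acs[i]) / speed)
        }
        hit <- tp$minutes >= a & tp$minutes < a + maturation
        d$fuzziness_sd[sel[hit]] <- d$fuzziness_sd[sel[hit]] +
          layout$params$fork_fuzz_add
      }
    }
  }
  d
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Simulate one MNase-seq sample
#'
#' Draws `depth` fragments from the layout's sources at one time point:
#' nucleosomal fragments (size truncated Normal(166, `size_sd`) on
#' [120, 250], midpoint = dyad + Normal(0, fuzziness)), sub-120 bp
#' footprint fragments at origin ACSs and Abf1 sites (size Uniform[60,119],
#' midpoint = site + Normal(0, 15)), and uniform background. Sampling
#' weight of any locus inside the replication front of a fired origin is
#' doubled (2x copy number). The per-fragment source is recorded.
#'
#' @param layout a `GenomeLayout`.
#' @param tp one time-point spec from [default_timepoints()].
#' @param depth total number of fragments to draw (> 0; 0 gives an empty set).
#' @param seed integer seed; output is deterministic given inputs + seed.
#' @param size_mean,size_sd nucleosomal fragment-size distribution (bp).
#' @param label sample label; defaults to `tp$label`.
#' @return A [fragment_set()] with a `source` column
#'   (nucleosome/footprint/abf1/background) and a `source_counts` attribute
#'   whose entries sum to `depth` exactly.
#' @export
simulate_sample <- function(layout, tp, depth, seed,
                            size_mean = 166, size_sd = 15,
                            label = tp$label) {
  stopifnot(depth >= 0)
  empty <- fragment_set(NULL, label, "simulated (empty)")
  empty[, source := character(0)]
  if (depth == 0) {
    setattr(empty, "source_counts",
            c(nucleosome = 0L, footprint = 0L, abf1 = 0L, background = 0L))
    return(empty)
  }
  set.seed(seed)
  p <- layout$params
  repl <- replicated_intervals(layout, tp)
  cn_of <- function(chrom, pos) {
    out <- rep(1, length(pos))
    for (cname in unique(chrom)) {
      sel <- chrom == cname
      out[sel] <- out[sel] + in_intervals(pos[sel], repl[[cname]])
    }
    out
  }

  d <- effective_dyads(layout, tp)
  w_dyad <- p$nucleosome_weight * d$occupancy * cn_of(d$chrom, d$pos)
  w_fp <- numeric(0); w_ab <- numeric(0)
  if (!is.null(layout$origins))
    w_fp <- footprint_occ_at(layout, tp$minutes) *
      cn_of(layout$origins$chrom, layout$origins$acs)
  if (!is.null(layout$abf1_sites))
    w_ab <- p$abf1_weight *
      cn_of(layout$abf1_sites$chrom, layout$abf1_sites$pos)
  repl_width <- vapply(repl, function(m)
    if (nrow(m)) sum(m[, 2] - m[, 1]) else 0, numeric(1))
  w_bg <- p$background_rate * (as.numeric(layout$chrom_lengths) + repl_width)
  names(w_bg) <- names(layout$chrom_lengths)

  w_all <- c(w_dyad, w_fp, w_ab, w_bg)
  if (sum(w_all) <= 0) stop("all sampling weights are zero")
  counts <- as.vector(rmultinom(1, depth, w_all))
  n_dy <- length(w_dyad); n_fp <- length(w_fp); n_ab <- length(w_ab)
  c_dy <- counts[seq_len(n_dy)]
  c_fp <- counts[n_dy + seq_len(n_fp)]
  c_ab <- counts[n_dy + n_fp + seq_len(n_ab)]
  c_bg <- counts[n_dy + n_fp + n_ab + seq_along(w_bg)]

  parts <- list()
  if (sum(c_dy)) {
    idx <- rep(seq_len(n_dy), c_dy)
    n <- length(idx)
    mid <- d$pos[idx] + round(rnorm(n, 0, d$fuzziness_sd[idx]))
    size <- as.integer(round(rnorm_trunc(n, size_mean, size_sd, 120, 250)))
    parts$nucleosome <- data.table(chrom = d$chrom[idx], mid = mid,
                                   size = size, source = "nucleosome")
  }
  if (length(c_fp) && sum(c_fp)) {
    idx <- rep(seq_len(n_fp), c_fp)
    n <- length(idx)
    mid <- layout$origins$acs[idx] + round(rnorm(n, 0, 15))
    size <- sample(60:119, n, replace = TRUE)
    parts$footprint <- data.table(chrom = layout$origins$chrom[idx],
                                  mid = mid, size = size, source = "footprint")
  }
  if (length(c_ab) && sum(c_ab)) {
    idx <- rep(seq_len(n_ab), c_ab)
    n <- length(idx)
    mid <- layout$abf1_sites$pos[idx] + round(rnorm(n, 0, 15))
    size <- sample(60:119, n, replace = TRUE)
    parts$abf1 <- data.table(chrom = layout$abf1_sites$chrom[idx],
                             mid = mid, size = size, source = "abf1")
  }
  if (sum(c_bg)) {
    bg <- list()
    for (ci in seq_along(w_bg)) {
      k <- c_bg[ci]
      if (!k) next
      cname <- names(w_bg)[ci]; L <- layout$chrom_lengths[[cname]]
      m <- repl[[cname]]
      # piecewise-uniform with weight 2 inside replicated intervals
      segs <- rbind(c(0, L, 1),
                    if (nrow(m)) cbind(m, 1) else NULL)  # extra copy
      sw <- (segs[, 2] - segs[, 1]) * segs[, 3]
      si <- sample.int(nrow(segs), k, replace = TRUE, prob = sw)
      pos <- round(segs[si, 1] + runif(k) * (segs[si, 2] - segs[si, 1]))
      bg[[cname]] <- data.table(chrom = cname, mid = as.integer(pos),
                                size = sample(20:250, k, replace = TRUE),
                                source = "background")
    }
    parts$background <- data.table::rbindlist(bg)
  }
  frag <- data.table::rbindlist(parts)
  # keep fragments fully inside the chromosome
  Lv <- layout$chrom_lengths[frag$chrom]
  frag[, mid := pmin(pmax(mid, 130L), as.integer(Lv) - 130L)]
  frag[, start := as.integer(mid - size %/% 2L)]
  frag[, end := start + size]
  out <- fragment_set(frag[, list(chrom, start, end, source)], label,
                      sprintf("simulated at %s (depth %d, seed %d)",
                              tp$label, as.integer(depth), as.integer(seed)))
  src_counts <- c(nucleosome = sum(c_dy), footprint = sum(c_fp),
                  abf1 = sum(c_ab), background = sum(c_bg))
  setattr(out, "source_counts", src_counts)
  out
}

#' Simulate a full cell-cycle time course
#'
#' One fragment set per (time point x replicate), with recorded seeds and
#' per-sample source counts so regeneration is byte-for-byte reproducible.
#'
#' @param layout a `GenomeLayout`.
#' @param timepoints from [default_timepoints()].
#' @param depth fragments per sample (scalar or one per time point).
#' @param replicates number of biological replicates (default 2).
#' @param seed master seed; per-sample seeds are derived as
#'   `(seed * 100003 + 1000 * replicate + timepoint_index) mod (2^31 - 1)`.
#' @param ... passed to [simulate_sample()].
#' @return List with `fragmentsets` (named `"<label>.rep<k>"`) and `truth`
#'   (layout, time points, per-sample seeds and source counts).
#' @export
simulate_timecourse <- function(layout, timepoints, depth, replicates = 2,
                                seed = 1L, ...) {
  if (!length(timepoints)) stop("need at least one time point")
  labels <- vapply(timepoints, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate time-point labels")
  depth <- rep_len(depth, length(timepoints))
  fsets <- list(); seeds <- list(); counts <- list()
  for (r in seq_len(replicates)) {
    for (i in seq_along(timepoints)) {
      s <- as.integer((as.numeric(seed) * 100003 + 1000 * r + i) %% 2147483647)
      lab <- sprintf("%s.rep%d", labels[i], r)
      fs <- simulate_sample(layout, timepoints[[i]], depth[i], seed = s,
                            label = lab, ...)
      fsets[[lab]] <- fs
      seeds[[lab]] <- s
      counts[[lab]] <- attr(fs, "source_counts")
    }
  }
  list(fragmentsets = fsets,
       truth = list(layout = layout, timepoints = timepoints,
                    seeds = unlist(seeds),
                    source_counts = do.call(rbind, counts)))
}
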