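---
title: "Quantifying cell-cycle chromatin dynamics at replication origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-cycle chromatin dynamics at replication origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oricycle)
```

## The measurement problem

Paired-end MNase-seq turns chromatin into a two-dimensional point cloud:
each sequenced fragment has a genomic midpoint and a length, and the
length reports what protected it — nucleosomes protect ~150–180 bp,
smaller DNA-binding factors (transcription factors, ORC, the pre-RC)
protect fragments under 120 bp. Around a DNA replication origin this
cloud has a stereotyped architecture: a nucleosome-free region (NFR)
centered on the ARS consensus sequence (ACS), flanked by well-positioned
−1/+1 nucleosomes, with an accumulation of sub-120 bp fragments at the
ACS where ORC and its successors sit.

`oricycle` quantifies how this architecture changes across a
synchronized cell-cycle time course (an α-factor arrest sample plus
samples every 10 min after release). Four derived signals carry the
analysis:

1. a **nucleosome score**: cross-correlation of the local
   midpoint-by-size fragment matrix with a 2D model nucleosome kernel;
2. a **replication copy number**: the ratio of windowed RPKM at time *t*
   to the α-factor (G1) sample, which corrects scores for the 1× → 2×
   DNA content change as forks pass;
3. a **small-fragment footprint density**: a Gaussian KDE of sub-120 bp
   fragment midpoints, calibrated against Abf1p binding sites;
4. a **Shannon entropy** of the nucleosome score in windows, measuring
   nucleosome disorganization.

## Depth equalization

MNase digestion extent, library preparation and sequencing depth all
shift the fragment-size spectrum between samples. Before any scoring,
samples of one replicate are equalized per fragment size: for every size
*s* in 20–250 bp, the minimum count across the replicate's time points
is found, and each time point is subsampled (uniformly, without
replacement) to exactly that count. Matched time points of the two
replicates are merged afterwards; replicates are not equalized against
each other. Fragments outside 20–250 bp are dropped at this stage, and
fragments with midpoints on chrM or in the rDNA repeat locus
(sacCer3 chrXII:451,575–489,469) are excluded up front. Each size draws
from its own seed derived from the master seed, so partial reruns
reproduce exactly.

## The nucleosome kernel

The kernel is learned from data, not assumed: fragments are stacked
around a reference set of nucleosome dyads (for real data, a
chemical-mapping dyad list; in synthetic mode, the generator's planted
dyads), producing an empirical (size × midpoint-offset) pileup. The
kernel is the bivariate Gaussian with the pileup's count-weighted
marginal means, zero correlation, and shrunken marginal variances —
1/16 of the marginal variance in the size dimension and 1/4 in the
position dimension. Shrinking sharpens the template toward the core of
the nucleosomal distribution so the cross-correlation peaks tightly at
dyads. The kernel is truncated to its grid (±100 bp offsets; sizes
20–250 bp) and renormalized to sum 1; only relative scores are used
downstream, so this fixes one convenient scale.

Because the kernel is a separable product of two 1D Gaussians, the 2D
cross-correlation factorizes exactly: fragments are first weighted by
the size marginal and accumulated per base, then cross-correlated with
the positional marginal. `score_nucleosomes()` and `nucleosome_track()`
both use this identity; the test suite checks them against a naive
double loop at 1e-9 relative tolerance.

Copy number divides the score per base. The ratio uses fragment-midpoint
counts in 1001 bp centered windows, converted to RPKM; windows clipped
at chromosome ends use their covered width, and positions whose
reference window is empty propagate `NA` rather than infinities. Note
that RPKM ratios are *relative*: since the sample total grows as the
genome replicates, a mid-S sample's ratios are uniformly depressed by
one over the mean copy number. Within-sample comparisons are unaffected
(the factor cancels), and the planted 2× is recovered directly when the
replicated fraction is small.

## Footprint density and calibration

The footprint track is a Gaussian KDE (bandwidth = kernel SD = 50 bp —
note some tools quote FWHM) of the midpoints of fragments *strictly*
smaller than 120 bp, estimated per chromosome and multiplied by
chromosome length so an unstructured chromosome has mean ≈ 1. For
integer midpoints this is computed exactly as a normalized discrete
Gaussian convolution of the per-base midpoint histogram. Because KDE
mass is conserved, per-sample totals cancel out of any within-sample
contrast; what remains of between-sample digestion variation is removed
by the Abf1p calibration: the mean occupancy within ±100 bp of a set of
Abf1p sites (cell-cycle-invariant occupancy) is computed per time point
and its reciprocal applied as a scale factor. Copy-number normalization
is applied first, then the factor is computed on the normalized track,
and every base in every site window counts equally (clipped windows
contribute their covered bases).

Per-origin density is the calibrated track value at the single ACS base
(an option averages ±N bp but defaults off). The per-time-point Spearman
correlation between log2 density and origin activation efficiency uses
ε = half the smallest positive density before the log; the transform is
rank-preserving for positive values, so ε matters only for zeros.

## Entropy of nucleosome organization

For a window X of n bases with nonnegative nucleosome scores, each
base's probability is its share of the window's total score, and the
disorganization is the Shannon entropy −Σ p·log p (natural log,
0·log 0 := 0). H is exactly scale-invariant, bounded by [0, log n], 0
for a point mass and log n for a uniform window. Windows with zero
total score are reported missing, not zero — absent coverage is not
"organized". Entropy is computed on copy-number-normalized nucleosome
tracks; the origin-anchored heatmap tiles ±15 kb around each ACS into
1 kb windows, pools windows across origins by the absolute distance of
the window center, averages per time point, and z-scores each distance
row (rows with zero variance are emitted as flagged zeros). Both the
pooled matrix and the per-origin array are returned. Active and passive
origin sets are the top and bottom 20% by efficiency.

## Dyad calls and class summaries

Aggregate profiles are extracted ±1 kb around each ACS, reversed for
origins whose T-rich strand is "−" so all origins read in the same
orientation, and averaged per footprint class ("G1&G2" vs "G1only").
The +1 (−1) dyad is the score argmax within 10–500 bp downstream
(upstream) of the ACS; 10 bp excludes the ACS footprint itself, 500 bp
covers all yeast +1/−1 positions, and exact ties break toward the ACS
(the innermost nucleosome is the named +1/−1). NFR width is the
dyad-to-dyad distance. Flat search windows flag a low-confidence call.
The footprint peak average fixes the peak on the *time-averaged* class
profile and reads the mean ±100 bp around it at each time point, so the
time series is comparable across time points.

## What the synthetic generator emulates

`build_layout()` plants the truth the pipeline is tested against:

* a nucleosome array with configurable spacing (default 165 bp) and
  positional fuzziness (default SD 10 bp); nucleosomal fragment sizes
  are truncated Normal(166, 15) on [120, 250] — the observed modal
  nucleosomal fragment size;
* origins of the two footprint classes, with −1 dyads 95 bp upstream
  and +1 dyads 160 bp ("G1&G2") or 126 bp ("G1only") downstream of the
  ACS, reproducing the wider NFR of the efficient class. Flanking
  dyads carry 1.25× occupancy — origin flanks are the well-positioned,
  strongly occupied nucleosomes, which keeps the innermost-maximum dyad
  call identifiable over the distal array;
* a transient +25 bp displacement of the "G1&G2" +1 nucleosome peaking
  10 min after release (pre-RC/pre-IC accommodation at the G1/S
  transition);
* footprint occupancy cycling with a 70 min period, peaking 20 min
  after release, with an origin-specific amplitude coupled to
  activation efficiency through a Gaussian copula (population Spearman
  0.6 by default) and a floor whose origin-specific scale is
  *uncoupled* — so the efficiency correlation genuinely peaks when the
  cyclic component peaks. The cyclic amplitude decays with a 60 min
  e-folding time, modeling the loss of culture synchrony that weakens
  second-cycle dynamics. "G1only" amplitudes are dampened 0.3×;
* deterministic replication: origins with efficiency ≥ 0.5 fire between
  15 and 40 min (earlier for more efficient origins), forks move at
  1000 bp/min, and a locus's replication time is the earliest arrival
  over fired origins — converging forks therefore terminate implicitly.
  Copy number doubles the sampling weight of every replicated locus.
  Nucleosomes replicated within the last ~10 min (10 kb behind the
  fork) carry +30 bp of extra fuzziness, modeling the disorganized
  chromatin behind the fork during nucleosome reassembly;
* Abf1-like sites with constant occupancy, placed in
  nucleosome-depleted gaps away from origins, as calibration anchors;
* uniform background fragments.

Fork speed, activation times, the restoration lag and the occupancy
waveform are conventions chosen to be realistic for budding yeast, not
measured facts; they define the study conditions under which the
pipeline's recovery is tested. Samples are drawn multinomially so
per-source counts sum exactly to the requested depth, and every draw is
seed-deterministic (per-sample seeds derive from one master seed).

The generator deliberately omits: sequence-level simulation (no
FASTA/FASTQ, alignment or mapping error), MNase sequence bias,
transcription-coupled nucleosome dynamics, stochastic per-cell firing,
and second-cycle replication. Passing tests therefore demonstrate that
the estimators recover planted truth under idealized fragment
statistics — not that real-data confounders (digestion bias, mappability,
copy-number heterogeneity across a desynchronizing population) are
handled beyond the corrections described above.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; midpoints use the floor
  convention `start + length %/% 2`; the rDNA exclusion interval is
  converted from its 1-based citation at the boundary.
* Exclusion and window counting are by fragment midpoint, consistent
  with midpoint-based scoring.
* The raw fragment-size mode is computed before size filtering;
  subsampling drops sizes outside 20–250 bp.
* KDE kernels are truncated at 4 SD and renormalized, making mass
  conservation exact up to chromosome edges.
* Degenerate cases fail loudly: empty pileups and zero-variance
  marginals reject kernel fitting; zero Abf1 occupancy rejects
  calibration; negative entropy inputs error; empty reference
  copy-number windows yield `NA`, never ±Inf.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
data at desk scale: chromosomes of 9 kb–1.2 Mb, 50–7300 planted
nucleosomes, 1–300 origins, and 1.5×10^5–4×10^6 fragments per sample;
the full time-course reproduction uses 16 time points × 2 replicates at
150,000 fragments each on a 640 kb chromosome (script) or 320 kb
(tests). These sizes were chosen so each planted effect is several
standard errors above counting noise while a complete run stays in the
minutes range on one CPU.

## Known limitations

* The RPKM copy-number ratio is relative to the sample mean, as
  discussed above; absolute 2× recovery assumes a mostly unreplicated
  genome at the measured time point.
* The copy-number estimate at the ACS itself is confounded by the
  time-varying footprint occupancy when footprint fragments are a large
  share of the 1001 bp window; this attenuates (but, being monotone,
  does not reorder) per-origin density contrasts.
* With 10-min sampling and ~1 kb/min forks, the disorganization band
  behind a fork is observable at essentially one time point per locus;
  the distance-dependent entropy delay is therefore quantized to the
  sampling interval.
* Aggregate dyad calls assume the class-average profile has its
  innermost maximum at the ±1 nucleosomes; per-origin calls are noisier
  and are exposed separately.
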