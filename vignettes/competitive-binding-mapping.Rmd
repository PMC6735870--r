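---
title: "Competitive-binding optical DNA mapping with cbmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive-binding optical DNA mapping with cbmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmapr)
```

## The assay and the computational problem

Competitive-binding optical DNA mapping reads long-range sequence
information from single stretched DNA molecules. Two small molecules are
added together: YOYO-1, a bis-intercalating dye that fluoresces only when
bound to DNA, and netropsin, a non-fluorescent minor-groove binder with
strong affinity for A/T tracts. Netropsin outcompetes YOYO-1 on AT-rich
stretches, so when a labeled molecule is stretched in a nanofluidic channel
and imaged, AT-rich regions appear dark and GC-rich regions bright. The
intensity profile along the molecule — its *barcode* — is a continuous,
sequence-dependent fingerprint that can be matched against a barcode
predicted from a reference genome.

`cbmapr` implements the full computational chain: predicting theoretical
barcodes from sequence, reducing time-lapse images (kymographs) to
experimental barcodes, placing barcodes on a genome, attaching extreme-value
P-values, quantifying genome mappability in silico, and projecting
second-channel labels (e.g. DNA damage marks) onto genome coordinates. A
synthetic-data module generates genomes, planted fragments and simulated
kymographs with known ground truth, so the whole pipeline is testable
without any external data.

## The binding model

The theoretical barcode rests on a one-dimensional two-species hard-rod
lattice model at binding equilibrium. Each ligand occupies a contiguous
window of `footprint` basepairs (default 4 for both species: netropsin's
canonical minor-groove site and YOYO-1's bis-intercalation span). Bound
windows may not overlap. A window starting at position $i$ carries
statistical weight $K_i c$, the association constant times the free-ligand
concentration:

* netropsin: $K_i$ depends on the 4-mer at the window start. The exact
  published per-4-mer constants are not bundled; the default table gives
  $10^8\,\mathrm{M^{-1}}$ to all-A/T 4-mers and $10^5\,\mathrm{M^{-1}}$ to
  every other 4-mer, which reproduces the strong A/T discrimination that
  drives the barcode. The table is a plain named vector
  (`netropsin_affinity_table()`) and can be replaced wholesale by measured
  constants.
* YOYO-1: sequence-independent, default $K = 10^6\,\mathrm{M^{-1}}$.

Default concentrations are the standard labeling mix, 60 µM netropsin and
0.2 µM YOYO-1. Free concentrations are approximated by totals — with the
ligands in large excess over binding sites at assay dilution, depletion is
negligible. Windows containing N get zero weight for both species, so
unsequenced reference regions come out dark rather than bright.

The marginal probability that a basepair is covered by YOYO-1 is computed
exactly by a forward/backward partition-function recursion (a transfer
matrix over "bare / netropsin rod / YOYO rod" states). The partition
function grows geometrically, so the recursion runs on a rescaled linear
ring buffer with per-position log bookkeeping — exact up to floating point,
no saddle-point or mean-field approximation. `brute_force_occupancy()`
enumerates every legal placement configuration on short lattices and serves
as the independent oracle: the two agree to $10^{-10}$ per basepair on
hundreds of random sequences.

Model assumptions worth stating: binding is at equilibrium (the labeling
protocol incubates to equilibrium); ligand rods are rigid with a fixed
footprint; there is no cooperativity between neighbours beyond exclusion;
and sequence-dependent DNA mechanics (local persistence length,
YOYO-induced elongation) are ignored, so the bp-to-nm mapping is uniform
along the molecule.

## From occupancy to a barcode

The microscope blurs the per-bp coverage with a point-spread function
modeled as a Gaussian, default $\sigma = 110$ nm. With a DNA extension of
0.2 nm/bp in 100×150 nm² channels and 160 nm camera pixels, one pixel
covers 800 bp and the PSF is 550 bp ($\approx 0.7$ px). The blurred profile
is integrated over pixel bins; each pixel value is the kernel-mass-weighted
mean of the coverage in its bin. At molecule ends the truncated kernel is
renormalized, which avoids artificially dark ends. Finally every barcode is
z-normalized (mean 0, sd 1) per molecule, making downstream Pearson
matching invariant to illumination and gain.

The bp-per-pixel value is the single coupling constant between image space
and genome space. In experiments it is calibrated per run from co-loaded
λ-phage DNA (48,502 bp): `calibrate_bp_per_pixel(median_lambda_extent_px)`.

## Kymographs to experimental barcodes

A kymograph stacks one intensity row per time frame. Thermal fluctuation
moves the molecule a few pixels between frames, so rows are aligned before
averaging: each row is shifted by the integer offset (bounded by
`max_shift = 10` px) that maximizes its Pearson correlation with the
running median of the rows already aligned, processed center-out. Ties go
to the smaller absolute offset, then the negative one, making alignment
fully deterministic. Subpixel alignment was deliberately left out: at PSF
widths below one pixel the payoff is small and integer shifts conserve row
content exactly (the aligned matrix is only ever a repositioning of the
original values).

The aligned rows are averaged over the first `n_frames` (default 10, the
standard acquisition depth; a single frame skips alignment), cropped to the
pixels covered by every used row — zero-padding would distort Pearson
scores — and z-normalized. Molecule ends are found on the *raw* averaged
trace by half-max thresholding between the background (median of the row
flanks) and the molecule plateau (median of the central region), after mild
Gaussian smoothing (σ = 2 px). The molecule interval runs from the first to
the last half-max crossing: a barcode legitimately dips to background level
inside AT-rich regions, so interior dips must not be read as molecule ends.

## Matching: position × orientation × stretch

An experimental barcode is placed on the genome by evaluating the Pearson
correlation against every same-length window of every chromosome's
theoretical barcode, for the original and the flipped (reversed) barcode,
over a grid of stretch factors (default ±5% in 1% steps, symmetric about
1) that absorbs residual extension variation between experiments. The
stretch is applied to the query by linear-interpolation resampling — one
fixed genome representation, many cheap query resamplings. The global
maximum $C_{\max}$ is the placement; ties break deterministically (lower
chromosome, lower start, forward before flipped, stretch nearer 1).

The scan is computed from prefix sums (window means and variances) and an
FFT cross-correlation against a per-reference cached spectrum, padded to a
5-smooth length; forward and flipped cross-correlations share one complex
inverse transform. A naive two-pass implementation is kept in the test
suite as the oracle; the two agree to $10^{-12}$. Windows with zero
intensity variance (long N runs) are excluded with a $-\infty$ sentinel
rather than letting NaNs propagate. A placement is counted correct when it
lands on the true chromosome within 20 pixels of the true start, in
leftmost-window coordinates for both orientations.

## Significance: an extreme-value null

$C_{\max}$ from a genome-wide search is a maximum over an enormous number
of correlated correlations, so raw correlation values carry no significance
on their own. The null model asks: how well would a *random* molecule of the
same length match this genome under the same search? Null queries are
random DNA sequences of the equivalent bp length pushed through the full
theory model — not permuted pixels, because the PSF imposes pixel
autocorrelation that permutation would destroy — and matched with the same
stretch/flip grid (the conservative choice: the null enjoys every freedom
the real query has).

The null $C_{\max}$ sample is Fisher-z transformed and fitted with a Gumbel
law by maximum likelihood, the natural family for maxima; a
Kolmogorov–Smirnov distance against the fitted law is stored as a
diagnostic, and an empirical-quantile fallback (`p_value_empirical()`) is
available. The fitted tail is what makes a $10^{-6}$ threshold usable: no
feasible number of null draws reaches it empirically. On fresh null draws
the fitted P-values are uniform to KS $< 0.05$ at $R = 2000$, and at fixed
$C_{\max}$ longer queries give smaller P-values, as they should — a longer
barcode carries more information. Null models are cached per query-length
bucket (25 px) per genome.

The default decision threshold is $P < 10^{-6}$, the level at which false
positives vanish in validation while long (multi-hundred-kb) molecules are
retained; it is a config knob like everything else.

## Mappability and the fragment-length sweep

`classify_mappability()` reproduces the uniqueness experiment: cut the
genome into fragments of length $L$ (default 333 kb — the average
experimental molecule — in random-phase or deterministic tiled mode),
compute each fragment's best *off-origin* $C_{\max}$ with all starts within
±20 px of its true origin masked, and call a fragment non-mappable when
that score exceeds 0.81, the empirical mean $C_{\max}$ of well-mapped
molecules: its barcode then has a doppelgänger elsewhere. The report
carries the mappable genome fraction and merged non-mappable intervals.
Noise-free fragments are used — conservative for uniqueness, since noise
only lowers off-origin correlation. `sweep_pvalue_length()` runs the
companion question: the smallest fragment length at which every sampled
noise-free fragment clears the P-value threshold.

## The damage channel

A second fluorescence channel (e.g. nick-translation-labeled damage sites)
is processed per molecule: average the raw frame stack, extract the
intensity trace by averaging a 5-px transverse band along the ROI, smooth
with a Gaussian of σ = 8 px, subtract the background trace taken from a
parallel band offset above the ROI, and normalize to the maximum. The
phrase "averaging above the ROI" admits two readings; smoothing the signal
then subtracting the raw background is the default, with
`mode = "subtract_smoothed_background"` as the alternative. Peaks are
local maxima above 0.3 of the trace maximum, greedily thinned to ≥ 4 px
separation — invented defaults, clearly labeled as such, since the assay
displays traces rather than prescribing a peak rule. Called peaks are
projected through the molecule's match result (stretch scaling, axis
reversal for flipped placements) onto genome coordinates; peaks outside
the matched interval are flagged, never silently dropped.

## The synthetic-data generator

The generator emulates the experimental regime: human-like GC content
(0.41), fragments of ~333 kb (415 px at 800 bp/px), additive iid Gaussian
pixel noise with sd chosen from the analytic relation
$\rho = 1/\sqrt{1+\sigma^2}$ so the planted cohort's mean $C_{\max}$ sits
at the empirical 0.81, stretch perturbations within ±4%, flips with
probability 0.5, 10 frames per molecule with 1 px/frame random-walk drift,
and Poisson-placed damage sites with Gaussian spot profiles at a chosen
SNR. Every generator is a pure function of its seed.

What it does *not* emulate: photon/EMCCD noise statistics (noise enters at
the pixel-barcode level, for speed and analytic control), polymer dynamics
of confined DNA, photobleaching, focus drift, or chimeric/overlapping
molecules. Passing tests therefore demonstrate the correctness and
statistical calibration of the algorithms under the stated noise model,
not robustness to every instrumental artifact of real data.

## Numerical choices and degenerate inputs

* Partition functions in a rescaled linear domain (threshold $10^{250}$)
  with per-position logs; exact, overflow-free.
* Truncated-Gaussian kernels renormalized at edges, kernel reach 6σ
  (truncation error $< 10^{-8}$ of mass).
* Zero-variance scan windows → $-\infty$ sentinel; a zero-variance query
  or an all-flat reference raises a classed error
  (`cbmapr_degenerate_barcode`, `cbmapr_degenerate_reference`).
* Constant traces cannot be z-normalized and are rejected rather than
  returning NaNs.
* $C_{\max}$ values are clamped to $[-1, 1]$ before Fisher-z; exact ±1
  (noise-free self-matches) map to the extreme finite z.
* All genomic coordinates are 0-based half-open; flipped placements are
  reported in leftmost-window coordinates so orientation never changes the
  coordinate convention.
* Ties anywhere (alignment shifts, argmax placements) break by fixed
  documented rules, making every pipeline stage deterministic given a seed.

## Problem sizes used by the tests and the acceptance script

Chosen once to mirror the study conditions at desk scale: oracle
equivalence on 200 random sequences of ≤ 14 bp; scan oracle on 100 random
pairs; planted-fragment recovery with 100 fragments of 415 px on a 30 Mb
synthetic genome; P-value calibration with an 800-draw fit evaluated on
2000 fresh draws of 100 px queries against a 2 Mb genome, plus a 150-draw
null at 415 px on the 30 Mb genome for threshold behavior; mappability on
a 30 Mb genome carrying one duplicated 2 Mb block, cut into 300 kb tiles;
damage projection on six molecules (both orientations) at SNR 12.

## Known limitations

* The netropsin affinity table is a two-level A/T-discrimination default,
  not a measured per-4-mer set; swap in measured constants for quantitative
  work on real genomes.
* The Gumbel null is a modeling choice for the tail beyond empirical
  reach; its calibration is verified in the bulk and the extreme tail is
  extrapolation, as with any fitted null.
* Integer-pixel kymograph alignment bounds registration accuracy at half a
  pixel per frame.
* Mappability with noise-free fragments slightly overstates mappable
  fractions relative to noisy molecules near the threshold.
* Single-Gaussian PSF; no camera transfer function beyond it.
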