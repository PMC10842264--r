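---
title: "Identifying proteins in density segments by exhaustive rigid-body screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying proteins in density segments by exhaustive rigid-body screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denscan)
```

## The model

A density segment is a 3D scalar field $t(v)$ on a regular lattice with
isotropic voxel size $h$ (Å) and a physical origin anchoring voxel
$(1,1,1)$. A candidate structure is a set of weighted point atoms. To
compare the two, each atom is blurred into an isotropic Gaussian whose
Fourier amplitude falls to one half at spatial frequency $1/\mathrm{res}$:

$$p(x) = \sum_a \frac{w_a}{(2\pi\sigma^2)^{3/2}}
         e^{-\|x - y_a\|^2 / 2\sigma^2},
  \qquad \sigma = \frac{\mathrm{res}}{\pi}\sqrt{\tfrac{\ln 2}{2}}
         \approx 0.187\,\mathrm{res}.$$

The same convention defines `lowpass_filter()`
($H(k)=e^{-\ln 2\,(k\,\mathrm{res})^2}$), so filtered experimental maps
and simulated probes live on a common resolution scale. Kernels are
truncated at $4\sigma$ per axis and renormalized (mass loss before
renormalization < 0.02%).

A pose is a proper rotation $R$ about the model centroid followed by a
translation: $x \mapsto R(x - c) + c + \tau$. Two scores are reported for
a pose, both over the full box after the density cutoff is applied to the
target:

$$\mathrm{CC} = \frac{\sum_v t\,p}
  {\sqrt{\sum_v t^2 \sum_v p^2}} \in [-1, 1], \qquad
  \mathrm{CC}_\mathrm{raw} = \sum_v t\,p .$$

The normalized score is bounded by Cauchy–Schwarz and invariant to
rescaling either map; the raw overlap is not, and a probe with, say, ten
times the target's mass readily exceeds 1 — reproducing a well-known
artifact of unnormalized correlation ranking. Libraries are always ranked
by the normalized score; both are reported.

## The search

`fit_model()` solves the 6D problem in stages:

1. **Orientation lattice.** `generate_rotations(step)` builds a
   deterministic quasi-uniform cover of SO(3): symmetry axes on a
   spherical spiral (poles included), each carrying a golden-offset ring
   of in-plane angles; the identity is always a member. The closed-form
   count is `round(360/step) * round(41253/step^2)` (4392 at 15°, 552 at
   30°); the measured covering radius against Haar-random rotations is
   about 0.8× the nominal step, well inside the documented bound of 1.5×.
2. **Translation scan.** For each candidate rotation the atoms are
   blurred onto the target lattice and cross-correlated with the target by
   FFT, yielding the score of every integer-voxel displacement at once.
   Displacements that would push the blurred model outside the box are
   excluded: a cropped segment carries no information there, and the
   restriction makes the target-sized circular FFT exact (no wrap-around
   contamination). Two numerical choices matter at this step:
   * *Search smoothing.* At the protocol's operating point the kernel
     ($\sigma \approx 1.12$ Å at 6 Å resolution) is narrower than the
     voxel (2.612 Å), so lattice scores depend strongly on the sub-voxel
     phase of the optimum. The scan therefore blurs probes by an extra
     0.45 voxel **during the search only**, and additionally estimates
     each rotation's sub-voxel peak height by log-parabolic interpolation
     (exact for a Gaussian peak). Without both, rotation ranking rewards
     gridding luck; measured on noiseless rotated targets, the raw lattice
     argmax can land on a 180°-flipped pose.
   * *Exact final scores.* All reported scores are re-evaluated in double
     precision with the exact kernel at the final pose; the smoothed
     landscape is never reported.
3. **Local polish.** The best few mutually distant lattice orientations
   (more when the lattice is coarse) are polished by a shrinking-step
   local search over single-axis rotation perturbations — a sampled
   search, no gradients — and the winner, chosen by its exact re-scored
   correlation, receives a final exact 6D pattern-search refinement over
   rotation and translation. Sub-voxel translation additionally uses
   log-parabolic interpolation of the correlation peak. On noiseless
   rotated 3-helix-bundle targets this pipeline recovers poses to ~0.1°
   and ~0.05 voxel, with CC ≈ 0.998 (the remainder is the cutoff
   conditioning of the target, see below).
4. **Library mode.** `scan_library()` uses a two-stage rotation scan by
   default (`search = "two_stage"`): a coarse lattice at twice the step
   ranks orientation neighborhoods, and only the best `keep = 6`
   neighborhoods are rescanned with the full-step lattice (radius
   `neighborhood = 1.5` steps). The final pose is always a member of the
   full-step search space scored identically; only global exhaustiveness
   is traded. The same trade is made by the established density-docking
   tools, which refine a peak list rather than report the raw exhaustive
   argmax. `fit_model()` alone defaults to the exhaustive single-stage
   scan (`search = "full"`).

Ties are broken deterministically: by unnormalized score, then rotation
index, then (in rank tables) model id. Screens are bit-reproducible and
invariant to library file order.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `resolution` | 6.0 Å | blur scale of probes; must be ≥ 2·voxel (Nyquist) |
| `step_deg` | 15° | nominal orientation sampling step |
| `cutoff` | 0 (benchmarks: 0.0025) | target densities ≤ cutoff are zeroed before scoring |
| `mode` | `"standard"` | `"laplacian"` applies a discrete 6-neighbor Laplacian to both maps before correlation (surface contrast) |
| `mirror` | `FALSE` | also search the mirror image; never silent, the result is flagged |
| `weight_mode` | `"unit"` | `"mass"` weights atoms by element mass |

The mirror option exists because segmentation pipelines can hand over
maps of either hand; mirroring is exposed as an explicit flag rather than
applied silently. Whether a screen should rank by normalized or raw
correlation is settled here in favor of the normalized score (the raw
overlap is reported alongside): the raw score's scale depends on probe
mass, which is exactly the >1 pathology.

## The synthetic benchmark

`make_benchmark_case(seed, n_decoys, snr)` emulates the study conditions
of a control experiment at desk scale:

* target frame 48³ voxels at 2.612 Å/voxel (the calibrated pixel size of
  the emulated imaging setup), resolution 6 Å, step 15°;
* truth: an antiparallel 3-helix bundle (30 residues/helix, 11 Å axis
  spacing) with seeded per-helix phases *and axial staggers* — at
  intermediate resolution helices are nearly featureless rods, and an
  unstaggered symmetric bundle would make orientation recovery ill-posed
  by construction;
* the truth is rotated by a Haar-random rotation, translated by up to
  ±5 Å, simulated, cutoff-conditioned at 0.0025 (the bundles' feature
  contour, about a twentieth of peak density), then corrupted with white
  Gaussian noise of standard deviation RMS(signal)/SNR. At SNR 1 the
  cutoff sits at ~2.8 noise standard deviations, so thresholding removes
  almost all pure-noise voxels while costing under 0.3% of the signal's
  own self-correlation — which is why noiseless self-fits report CC
  ≈ 0.998 rather than 1.0 exactly;
* decoys mix random helix bundles (2–4 helices — deliberate same-fold
  confounders, the hardest discrimination) and compact pseudo-globular
  Cα blobs, 60–150 atoms.

Every generator is a pure function of its arguments and seed.

What passing these benchmarks shows: the engine recovers planted poses to
a fraction of the sampling step, discriminates the generating model from
same-fold confounders under calibrated white noise, and is deterministic.
What it does not show: robustness to tomographic artifacts (missing
wedge, CTF, non-white noise), to segmentation errors, or to the
conformational mismatch between predicted models and real densities —
white Gaussian noise plus low-pass is the stated noise model, and
automatic segmentation is out of scope.

## Numerical choices and degenerate inputs

* MRC2014 I/O: float32 mode 2, little-endian canonical (big-endian reads
  supported), x fastest; the MRC2014 ORIGIN record is the single frame
  anchor and nstart words are ignored; anisotropic voxel sizes are a
  format error naming the field.
* `apply_edge_guard()` uses a relative epsilon of 1e-3 over the cutoff
  (absolute 1e-9 when the cutoff is zero); `autocrop()` of a guarded grid
  is dimension-preserving for any grid.
* FSC shells are one Fourier voxel wide; threshold crossings are linearly
  interpolated between shells; self-FSC is 1 in every shell and the
  statistic is invariant to positive rescaling of either map.
* Degenerate inputs error early and descriptively: all-zero targets,
  models entirely outside the frame, empty masks and empty libraries, a
  resolution below Nyquist, rotation sets with non-positive step.
* Library screens never die on one bad file: unreadable models are
  skipped with a warning and enumerated in the result.

## Problem sizes used in the shipped tests

Unit tests run on 8³–48³ grids with coarse (30°–90°) rotation lattices;
the end-to-end validation runs twenty 50-model screens at the full
operating point (48³, 15°, SNR 1), which completes in roughly a quarter
hour on a single CPU. A full proteome screen (tens of thousands of
models) is embarrassingly parallel across models; per-model scoring is
independent and the output order is defined by the sort, not by
completion order.
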