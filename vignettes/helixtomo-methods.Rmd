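---
title: "helixtomo: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{helixtomo: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixtomo)
```

This vignette is the package's own account of what it computes and why
the numerics are the way they are. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The scientific setting

Microtubules in drug-induced cellular protrusions can harbor actin
filaments inside their ~15 nm lumen. Cofilin decoration changes an actin
filament's helical symmetry: the per-subunit twist tightens from roughly
−167° (bare f-actin, rise ≈ 27.5 Å) to roughly −162° (cofilactin, rise ≈
28.5 Å). Because an actin-family filament appears in projection as two
long-pitch strands that cross periodically, the twist change shows up as
a shortened cross-over distance,

$$ c \;=\; \frac{\text{rise} \times 180}{180 - |\text{twist}|}, $$

valid for $90 < |\text{twist}| < 180$: ≈ 28.2 nm for cofilactin versus
≈ 38.1 nm for bare f-actin. This closed form is the package's internal
oracle: every Fourier-space measurement is checked against it.

The quantities the package computes are the ones such a study reports:
per-microtubule protofilament number and polarity (from classification
votes), cross-over distances (from layer lines), refined twist/rise
(from a symmetry grid search), resolution (FSC), and luminal-filament
occupancy/coverage/orientation statistics with per-replicate mean ± s.d.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every recovery claim is made.

**Geometry.** A filament is a 1-start helical lattice: subunit $k$ at
azimuth $k\cdot\text{twist}$, height $k\cdot\text{rise}$, radius 25 Å
for actin. A microtubule with $N \in \{12..15\}$ protofilaments places
tubulin monomers at center radius $N\cdot 50/(2\pi)$ Å (50 Å lateral
spacing), 40.95 Å monomer spacing, and an inter-protofilament axial
stagger of $3\cdot 40.95/N$ Å — a 3-start approximation without a seam,
enough to reproduce the $N$-dependent diameter and moiré that
classification relies on.

**Density.** Subunits are isotropic Gaussian blobs. Each actin subunit
is rendered as a broad envelope (σ = 25 Å) *plus* a compact core
(σ = 10 Å); cofilin decoration adds an envelope (σ = 15 Å) and core
(σ = 8 Å) at radius 45 Å on the subunit azimuth, and tubulin uses a 20 Å
envelope. The core component matters: a single σ = 25 Å Gaussian at a
27.5 Å spacing attenuates the $1/\text{rise}$ lattice frequency by
$e^{-(2\pi\sigma/\text{rise})^2/2} \approx e^{-16}$ — such a map is a
featureless tube whose helical parameters are unrecoverable in
principle. Real subunits have internal contrast; the two-component blob
restores the lattice frequencies while keeping the envelope dimensions
(cofilin decoration still widens the filament). Blobs narrower than the
voxel are clamped to 0.85 voxel to avoid aliasing. Polarity is encoded
by a half-amplitude marker blob offset +8 Å along the axis, so a
polarity flip is physically detectable; flips are proper rotations (180°
about an axis normal to the filament), never mirror operations.

**Corruption.** White Gaussian noise is added in real space with
standard deviation `noise_sigma` × signal peak, then a missing wedge is
applied in Fourier space: with tilt axis $y$ and half-angle $\alpha$
(default 60°, matching a ±60° tilt series), all frequencies with
$|k_z| > \tan(\alpha)\,|k_x|$ are zeroed. The mask depends only on
moduli, so it is Hermitian-symmetric and the volume stays real. No CTF,
dose weighting, or reconstruction round-trip is simulated.

**Vote tables.** Multireference classification output is emulated
statistically: each filament draws a true (N, polarity) class from the
study's class fractions; each particle votes the truth with probability
`p_correct` (default 0.85), else uniformly among the remaining classes;
cross-correlation scores come from class-conditional normals truncated
at zero — correct votes ~ N(0.15, 0.03), wrong votes ~ N(0.10, 0.03),
chosen to straddle the 0.13 acceptance threshold rather than to emulate
any particular software's score scale.

**What passing tests do and do not show.** The generator produces ideal
lattices with white noise and a clean wedge. Real tomograms add CTF
modulation, correlated noise, lattice defects, tethering densities and
crowding; recovery on synthetic scenes therefore validates the
*algorithms* (thresholds applied correctly, geometry handled exactly,
estimators unbiased at adequate SNR), not the field performance of the
full experimental pipeline.

## The vote caller

Cleaning retains the best-scoring $\lceil 0.8 n \rceil$ particles
globally across the table (the order the original workflow implies),
with a stable tie-break (cc descending, particle id ascending).
Per-filament mode is available via `assignment_rule(clean_scope =
"per_filament")`.

A filament is assigned to its modal class when the winning fraction is
≥ 0.65, or ≥ 0.50 with the filament's overall cc score ≥ 0.13. Three
interpretations were genuinely open and are resolved as follows:

* "overall cross-correlation score" = the **mean** cc of the filament's
  *retained* particles (median available via `cc_stat`); evaluated after
  cleaning, following the stated order of operations;
* an exact modal tie is undetermined — neither criterion can
  distinguish the tied classes;
* filaments emptied by cleaning are undetermined.

Undetermined filaments are excluded from all downstream quantifications.
Polarity unification applies the 180° flip about the second Euler angle
to the particles' *original* orientations (kept in `rot0/tilt0/psi0`),
which makes the operation idempotent. Protrusion summaries require at
least 2 microtubules of resolved orientation, else the protrusion is
excluded.

## Cross-over measurement

The protocol mirrors the Fourier workflow used on real tomograms: mask
with a soft cylinder (value 1 inside radius $r_0$ = 14 nm, Gaussian
falloff with σ = $r_0/4$), form the side-view projection, embed in a
512-pixel frame, take the power spectrum, bin 2× to 256, and convert the
equator-to-layer-line distance $L$ with $c = B\,p/L$.

Two numerical points:

* **Binning is center-preserving**: binned pixel at offset $L$ from the
  spectrum center covers original offset $2L$ with (¼, ½, ¼) weights, so
  the DC term stays at a bin center and $c = B\,p/L$ is exact on the
  binned grid. Naive 2×2 block averaging shifts the frequency grid by
  half a pixel and systematically misassigns the peak bin.
* **The profile is averaged over a wide equatorial band** (±48 binned
  pixels). The cross-over layer line of a two-start-appearing helix
  carries Bessel order 2 and peaks well off the meridian (first maximum
  of $J_2$ at the filament radius, ≈ 25 binned pixels here); a
  meridian-only profile misses it.

The peak must exceed 3× the local background median within the search
band (default 3–40 binned pixels), else the function reports "no layer
line" — pure noise volumes fail loudly rather than returning a number.
At bin4 sampling (11.81 Å/voxel) the measured cofilactin value is the
oracle 28.19 nm quantized to the binned grid: $256 \times 1.181 / 11 =
27.49$ nm.

## Helical-symmetry grid search

`symmetry_grid_search` maximizes a real-space correlation between the
map and its transform by (twist, rise) within a 120 Å cylinder, coarse
grid 1° × 0.5 Å over twist −200…−100° and rise 1–40 Å, then local
refinement at 0.1° × 0.1 Å.

The symmetry contrast of a smooth filament map is shallow — order 0.02
in correlation units — so the scoring engine is built to keep every
numerical bias well below that:

* the map is cosine-tapered at its z ends and the **rise translation is
  applied exactly** as a Fourier phase ramp (the Gaussian-blob maps are
  bandlimited, so the circular shift is exact). Fractional-voxel linear
  interpolation along z would bias the rise optimum by several tenths
  of an Ångström, favouring near-integer-voxel rises;
* the **twist rotation is split symmetrically** (+twist/2 on one copy,
  −twist/2 on the other, bicubic resampling), so both copies suffer
  identical in-plane interpolation attenuation and it cancels from the
  normalized correlation;
* the correlation runs over a **fixed central z window** (excluding the
  taper and the largest trial shift), so the support does not change
  with the trial rise;
* voxels within 2.5 voxels of the axis are excluded — they barely move
  under rotation, so on noisy maps their noise correlates with itself
  through the interpolation kernel and biases the score toward
  rotation-only transforms.

A surface whose coarse dynamic range is below 0.05 is flagged
degenerate (a uniform cylinder correlates equally under every
symmetry). On the 64³, ~5.9 Å/voxel noiseless maps used in the
acceptance run, the search returns the generating parameters exactly at
the fine-grid resolution.

**Noise limitation.** A single 64³ filament (~13 subunits) carries
limited twist information. With white noise at 5% of the signal peak
the optimum stays within ±0.5° / ±0.3 Å (tested); at substantially
higher noise the score fluctuation across the ~8,000-cell coarse grid
exceeds the symmetry contrast and recovery degrades, with a systematic
pull toward the broad ridge of the smooth tube component. In practice
the search is meant for *averaged* maps (as in the original workflow,
where it runs on a subtomogram average of thousands of particles), not
raw noisy subvolumes; a Gaussian `lowpass` option is provided for
moderately noisy inputs.

## Morphology consensus

The nine-run consensus emulates the classification protocol: runs with
5, 10 and 20 classes, each nominally at reference twists −162°, −165°,
−167° (the study's values; the middle one represents neither morphology).
Actual helically constrained 3D classification is out of scope, so each
run is a surrogate: particles are clustered by k-means on
**translation-invariant amplitude-spectrum features** (particles of one
morphology share layer-line content — cross-over frequency, decoration
width — but differ in azimuthal phase and axial register, so clustering
raw pixels would split and blur classes), each class average is mapped
to {cofilactin, f-actin, other} by correlation against rendered
template features, and particles inherit their class's label. The run's
class count and reference twist select the k-means initialization
stream, which is where run-to-run variability enters; at high SNR the
nine runs typically agree (s.d. near zero), below the run-to-run spread
the by-eye protocol reports. Manual class→morphology maps can be
supplied directly to `consensus_percentages`.

Percentages are computed per condition × replicate per run, then
averaged across runs (mean ± s.d. over the 9 runs); the three morphology
percentages sum to 100 within each run by construction.

## Statistics conventions

* Lengths in tables are nm; map-level quantities (rise, diameters,
  resolution) are Å. Traces are nm; the conversion is exactly ×10.
* Occupancy counts a microtubule once however many filaments it hosts.
  Coverage sums filament lengths, warns above 1.05× the microtubule
  length (tracing inconsistency) and clamps to 1.
* Replicate summaries use the sample s.d. (n−1); a single replicate
  reports `NA`. Technical replicates are pooled before percentages.
* Host assignment uses the mean perpendicular point-to-axis distance
  with a hard 8 nm containment radius (the lumen is ~15 nm wide; the
  radius is exposed as a parameter since the original containment
  judgement was visual).
* Trace resampling uses parallel-transport frames: the frame's z axis
  follows the local tangent and the in-plane axes are transported
  without roll. Frenet frames were rejected — they are undefined on
  straight segments, which picked traces mostly are.
* Euler convention is intrinsic Z-Y-Z (rot, tilt, psi), degrees, tilt in
  [0, 180]; at gimbal-degenerate orientations `rot` carries the full
  in-plane angle and `psi` is 0. Angles are stored in degrees
  throughout; radians appear only inside trigonometry.

## Problem sizes

The shipped tests and the acceptance script use: 64³ maps (≈ 5.9
Å/voxel) for symmetry searches; a 48 × 48 × 512 box (≈ 600 nm) at bin4
sampling for the cross-over; 544 filaments × 40 particles for the vote
recovery; 2,000 particles × 9 runs for the morphology consensus. These
sizes put every statistical tolerance several standard errors wide while
keeping a full run in a few minutes on one CPU.

## Known limitations

* The microtubule lattice omits the seam and luminal tethering
  densities; no quantitative claim here depends on them.
* The missing wedge uses a single tilt axis and a sharp angular cutoff.
* FSC is computed without masking or phase-randomization correction;
  the 0.143 criterion is a configurable default.
* The symmetry search assumes the helical axis is z through the box
  center; align or resample first (`resample_trace` provides frames).
* Multi-start helices with independent per-start parameters are out of
  scope throughout.
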