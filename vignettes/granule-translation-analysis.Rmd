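---
title: "Mapping translation at RNP granule surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping translation at RNP granule surfaces: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(suntagr)
```

`suntagr` quantifies where mRNAs are translated relative to
ribonucleoprotein (RNP) granules in multi-channel 3D fluorescence
volumes, and how fast ribosomes elongate on them. This vignette
explains the models, the tunable parameters, the synthetic data that
everything is validated against, and the numerical choices made where
the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Coordinate conventions

Volumes are arrays indexed `[z, y, x]` with anisotropic spacing in nm
(default 150 × 42.5 × 42.5, typical of high-resolution confocal stacks
with 150 nm z-steps). Voxel `i` (1-based) is centred at
`(i − 0.5) · spacing`, so the image occupies the half-open physical box
`[0, n · spacing)` per axis. All user-facing coordinates are physical
nm in z, y, x order.

## The synthetic-data generator

`generate_phantom()` renders a three-channel volume — granule marker,
mRNA foci, nascent-protein foci — with exact ground truth:

* **Granules are spheres.** Real granules are irregular; spheres give
  closed-form signed distances (`|x − c| − r`), which makes every
  downstream stage checkable against an exact oracle. This trades
  realism for testability, deliberately.
* **Placement laws** position mRNA foci uniformly in the volume, in a
  Gaussian shell around granule surfaces (mean/sd in nm), uniformly
  inside granules, or as paired 3′-surface / 5′-outward doublets for
  co-localization phantoms.
* **Translation labels.** A configured fraction of mRNAs receives a
  protein partner within `pairing_dist_nm` (default 150). To keep the
  labels unambiguous under the 400 nm calling rule, every protein focus
  is kept at least `nontranslating_clearance_nm` (default 400) away
  from every non-translating mRNA; opposite-label mRNA foci are kept
  that far apart during placement. This constraint is geometrically
  infeasible for dense mixed-label populations inside a single small
  granule; the clearance is a config parameter so such phantoms can
  relax it, accepting rare chance co-localizations.
* **Optics and camera.** Foci and spheres are convolved with a
  separable anisotropic Gaussian PSF (default sigma 300/100/100 nm in
  z/y/x, a standard confocal approximation), then Poisson shot noise
  and additive Gaussian read noise are applied. Both noise sources can
  be switched off for linearity tests.
* All randomness flows from one explicit seed.

What the phantoms do **not** emulate: irregular granule morphology,
optical aberrations and resolution anisotropy beyond the Gaussian PSF,
autofluorescent background structure, chromatic misalignment, and
spot-intensity heterogeneity. Passing tests therefore demonstrate the
correctness of the computations, not robustness to every property of
real embryo images.

## Spot detection and fitting

Detection uses one band-pass filter throughout: a Laplacian-of-Gaussian
matched to the PSF. The blur step is renormalized at the volume borders
(division by the blurred unit volume) so near-border foci are not
attenuated; as a consequence, maxima on the outermost voxel shell are
suppressed (the renormalization can turn an object flank into a border
maximum). Foci whose intensity maximum falls within about two z-planes
of the stack border are not detectable — a documented blind margin.

The detection threshold follows a plateau heuristic: counts of local
maxima are scanned over a geometric threshold grid; on log–log axes the
count falls exponentially through the noise, flattens where every real
focus (and nothing else) is detected, and falls again. The selected
threshold is the smallest threshold of the longest run of grid
intervals with |Δlog count / Δlog threshold| below `plateau_tol`
(default 0.2, with a minimum run of 4 grid points). The heuristic is
qualitative in origin; both knobs are exposed. Because the filter is
linear and the automatic grid is built from filtered-response
quantiles, the selected threshold scales exactly with the image — a
property the tests assert.

Each candidate is refined by a least-squares 3D Gaussian fit (free
amplitude, centroid, per-axis sigma, constant background) in a
5 × 7 × 7-voxel window via Levenberg–Marquardt. Exactly symmetric
starts can produce a singular gradient on noise-free data, so the fit
retries from deterministically perturbed starts. Non-converged or
out-of-bounds fits are flagged and excluded downstream. On
well-separated foci at SNR ≥ 5 the suite verifies recall and precision
≥ 0.95 and per-axis RMSE < 0.3 voxel.

Movie linking is a deliberately simple mutual-nearest-neighbour linker
(max displacement 1 µm, one-frame gap closing, ties by smaller
displacement then lower index), with a strict `> 30` observed-frame
filter. It does not solve a global assignment problem and does not
handle splitting or merging.

## Granule segmentation and surface classification

Granules come from thresholding (fixed value or automatic). The
automatic path applies Otsu recursively while the above-threshold
fraction exceeds `max_fill` (default 0.25) — plain Otsu mis-splits the
heavily skewed histogram of a sparse-object volume — and then requires
the foreground to clear the background mean by `min_contrast` (4)
background standard deviations, returning an empty mask with a warning
otherwise. The machine-learning pixel classification used in practice
for irregular granules is intentionally out of scope; threshold
segmentation is evaluated only on phantoms where it is adequate.

Connected components use 26-connectivity; a granule voxel is *surface*
when any of its 6 face-neighbours lies outside the granule or it sits
on the image boundary, and *interior* otherwise (surface ∪ interior =
granule, disjoint). Both conventions are configurable; neither is
canonical, and the suite checks the classification against a
brute-force neighbour scan. Granules with any voxel on the image
border are flagged and their associated foci excluded from distance
statistics, so only fully captured granules contribute.

## Signed distance mapping

Each focus gets the minimum anisotropic distance from its centroid to
any surface-voxel *center*, signed negative when its containing voxel
belongs to a granule. Using voxel centers (not a sub-voxel iso-surface)
matches the pixel-list method the analysis reproduces; the price is a
discretization error on the order of half a voxel diagonal (~82 nm at
default spacing). One geometric subtlety is larger: for a sphere
centred in the volume, the polar cap occupies a single voxel plane at
150 nm axial spacing, and its surface-voxel centers sit up to a full
z-step inside the true surface, so the measured distance of a spot at
the sphere center is biased by up to ~85–150 nm depending on sub-voxel
centering. The implementation *is* the brute-force definition
(chunked vectorized search); the tests require exact agreement with an
independent exhaustive oracle.

Distance distributions are reported as relative-frequency histograms
with 25 nm bins aligned at zero, overlaid with a Gaussian KDE using
Scott's rule bandwidth (`stats::density(bw = "nrd")`; the choice is
exposed because no bandwidth is canonical).

Two nulls accompany every distance analysis. The rotation control maps
each focus to its image under a 180° in-plane rotation about the xy
center (z unchanged; an involution). The uniform control draws points
uniformly over the physical volume. A caveat the tests respect: foci
cluster on granule surfaces, so after rotation whole clusters enter or
miss the surface shell together. Binomial error bars on the rotated
surface-shell frequency are only valid when clusters are numerous —
the acceptance checks use a dense field (150 granules, ~22 µm crop,
2000 foci) matching that regime.

## Translation calling

An mRNA is translating when a protein focus lies within 400 nm
(closed bound: 400.0 matches). Matching is greedy one-to-one over
candidate pairs sorted by ascending distance — deterministic, with an
optimal bipartite assignment available behind a flag for comparison.
The 400 nm radius and the alternative 250 nm plateau value are both
plain parameters. Fractions are reported with numerator and
denominator, per region and per 25 nm signed-distance bin (sparse bins
flagged below `min_n`). Group comparisons use two-tailed Welch's
t-tests; replicate-level comparisons (superplots) test the per-embryo
means, never pooled spots, to avoid pseudo-replication. Two degenerate
conventions: two zero-variance samples with equal means give t = 0,
p = 1; with unequal means, p = 0.

## FRAP model and elongation rate

Assumptions (asserted, not enforced on data): ribosomes uniformly
distributed along the ORF; constant initiation and elongation; stable
epitope labelling on the FRAP timescale; immediate release at
termination. With an epitope array of `L1` codons and a downstream CDS
of `L2` codons, a complete bleach recovers in three phases:

* linear, `I(τ) = 2 v τ I0 / (L1 + 2 L2)` until intensity reaches
  `I0 L2 / (0.5 L1 + L2)` (at `τ = L2 / v`);
* quadratic slow-down,
  `I(τ) = I0 − I0 (L1 + L2 − v τ)² / (L1 (L1 + 2 L2))`;
* plateau at `I0` from `τ = (L1 + L2)/v`.

The quadratic phase follows from the same uniform-density assumptions
by continuity; an event-driven simulator of individual ribosomes
(steady-state occupancy `Poisson(d (L1 + L2))`, initiations at rate
`d·v`, epitope signal = codons traversed inside `[0, L1]` since the
bleach) is kept as an independent oracle, and the suite requires
frame-wise agreement within 3 SEM at 10⁴ mRNAs. Incomplete bleaching
is modelled as an additive residual offset capped at `I0`; a
multiplicative model would bias the fitted slope by `(1 − residual)`,
which is why the additive form was chosen.

`fit_elongation_rate()` estimates `I0` as the prebleach mean, takes the
post-bleach frames strictly before the first crossing of the analytic
boundary (a changepoint detector would be less transparent and is not
what the procedure describes), fits an ordinary least-squares line with
free intercept — the intercept absorbs residual post-bleach signal
without changing the slope's meaning — and converts
`v = slope (L1 + 2 L2) / (2 I0)`. Rates are in codons/s (≡ amino
acids/s); lengths are accepted in codons, with nucleotides = 3 ×
codons. `L1` and `L2` have no canonical defaults; the configuration
defaults (200/400) are round numbers for simulation studies.

Ribosome occupancy: `d = F / (F0 (L2 + 0.5 L1))` — ribosomes inside
the epitope array carry on average half of it, hence the effective
length `0.5 L1 + L2` — with `d (L1 + L2)` ribosomes per mRNA and `3/d`
nt per ribosome. `F0` is estimated from a focus-amplitude sample as the
median of the lower component of a two-component Gaussian mixture;
unimodal samples are refused, and separations below twice the larger
component spread are flagged.

## Pixel co-localization

Pearson correlation is computed over the union of above-threshold
voxels of the two channels (Otsu or isodata — the insensitivity of the
result to the automatic method is itself a tested property), optionally
after subtracting a slice-wise morphological-opening background
(the specific background tool behind the published analysis is not
specified; opening with a configurable disc is a standard stand-in).
Granule-centered averaging samples a seeded subset of granules whose
box (default 9 × 21 × 21 voxels; the published figure does not state a
box size) fits inside the volume and averages sub-volumes voxel-wise.
Line profiles use trilinear interpolation between physical endpoints.

## Pipeline, determinism, problem sizes

`run_pipeline()` chains simulate/load → segment → detect → map
distances → call translation → report, writing CSV/JSON plus a
provenance record (config hash, seed, package version — deliberately no
timestamp, so reruns are byte-identical; the suite asserts this).
A YAML config mirrors every parameter; a thin wrapper script lives at
`inst/scripts/run-pipeline.R`.

Test and acceptance problem sizes were chosen to make the statistical
assertions sharp at desk scale: 20 random masks × 200 spots for the
distance oracle; 10⁵ points for the uniform-control CDF (closed-form
comparison restricted to the radius range where the growing ball stays
inside the box, where the CDF is exactly `(4/3)π(r+s)³/V`); 20 seeds ×
1000–2000 mRNAs for fraction recovery; 100 seeds at 2% noise and 10⁴
mRNAs for the FRAP checks; 10⁴ replicates for Welch calibration.

## Known limitations

* Distance accuracy is voxel-limited (see above); no sub-voxel
  iso-surface and no 2D mode.
* Detection has a ~2-z-plane blind margin at stack borders and assumes
  diffraction-limited, roughly PSF-shaped foci.
* Threshold segmentation will not match trained pixel classifiers on
  irregular, textured granules.
* The linker is frame-to-frame greedy; crossing trajectories closer
  than the PSF or faster than `max_disp` per frame are not resolved.
* The FRAP model ignores scFv binding kinetics, photobleaching during
  imaging, and initiation-rate changes; rates outside the assumed
  steady state will be misestimated with no internal warning.
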