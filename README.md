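# suntagr

Quantitative analysis of single-molecule translation imaging at RNP
granule surfaces, in R.

In *Drosophila* germplasm, maternal mRNAs such as *nanos* concentrate in
ribonucleoprotein (RNP) condensates — germ granules — and are
translated there. Imaging experiments that combine smFISH (single
mRNA molecules), a SunTag nascent-peptide reporter (translation sites)
and a granule marker ask *where*, relative to the granule surface,
translation happens, *what fraction* of mRNAs are engaged, and *how
fast* ribosomes elongate. `suntagr` implements that analysis chain as a
tested, reusable package, together with a synthetic-data generator that
renders 3D image phantoms and FRAP curves with exact ground truth so
every stage can be validated without access to microscope data.

## What the package computes

**Signed surface distances.** Granules are segmented from their marker
channel and labelled in 3D; each granule's voxels are split into
surface (a 6-neighbour lies outside) and interior. For every focus the
minimum anisotropic Euclidean distance to any surface-voxel center is
computed and signed: negative inside a granule, positive outside.
Granules touching the image border are excluded. Distances are
summarized as relative-frequency histograms (25 nm bins) with a KDE
overlay, with two null controls: a 180° in-plane rotation of the focus
channel and uniformly distributed random points.

**Translation calling.** An mRNA focus is called translating when a
nascent-protein focus lies within 400 nm (closed bound, one-to-one
greedy matching by ascending distance). The package reports translating
fractions overall, per region, and per signed-distance bin, and
compares groups with two-tailed Welch's t-tests (including
replicate-level "superplot" comparisons).

**FRAP kinetics.** For a polysome carrying an epitope array of `L1`
codons followed by a CDS of `L2` codons, recovery after photobleaching
is piecewise: a linear phase with slope

    dI/dt = 2 v I0 / (L1 + 2 L2)

lasting until the intensity reaches `I0 L2 / (0.5 L1 + L2)`, a
quadratic slow-down, and a plateau at `I0` from `t = (L1 + L2)/v`. The
elongation rate `v` (codons/s) is estimated from the linear phase. An
event-driven simulator of individual ribosomes serves as an
independent oracle for the analytic model. Ribosome occupancy follows

    F = F0 · d · (L2 + 0.5 L1)

where `F` is polysome intensity, `F0` the single mature-peptide
intensity and `d` the ribosome density per codon (`3/d` nucleotides per
ribosome).

**Pixel co-localization.** Pearson correlation over automatically
thresholded voxel sets (Otsu or isodata), granule-centered image
averaging, and line-intensity profiles.

## Worked example

```r
library(suntagr)

cfg <- phantom_config(seed = 9, shape_zyx = c(20, 160, 160),
                      n_granules = 8, n_rna_spots = 60,
                      granule_radius_range = c(200, 300),
                      placement_law = placement_uniform_volume(),
                      gaussian_noise_sd = 1)
res <- run_pipeline(pipeline_config(out_dir = "out", phantom = cfg,
                                    seed = 9))
res$summary
```

prints (abridged):

```
$n_granules
[1] 8
$n_rna_spots
[1] 43
$translating_fraction
[1] 0.3953488
```

43 of the 60 simulated mRNA foci were detected and fitted (the rest lie
too close to the stack borders or to each other), and 39.5% of them
co-localize with a nascent-protein focus within 400 nm — the simulated
truth is 40%. `out/` contains the spot tables, the signed-distance
records and histogram, the translation calls and a provenance record;
rerunning with the same configuration reproduces every file
byte-for-byte.

Estimating an elongation rate from a simulated bleach:

```r
curve <- simulate_frap_curve(frap_sim_config(v = 4, L1 = 200, L2 = 400,
                                             noise_sd_fraction = 0.02))
fit <- fit_elongation_rate(curve, L1 = 200, L2 = 400)
fit$v_hat
#> [1] 3.95613
```

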