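# Output formats

All coordinates are physical nanometres, axis order z, y, x,
voxel-center convention: voxel i (1-based) is centred at
(i − 0.5) · spacing, the volume spans [0, n · spacing) per axis.

## Image stacks (`write_image_stack` / `read_image_stack`)

Multi-page TIFF, 32-bit float, pages are z-slices in channel-major
order (all z of channel 1, then channel 2, ...). Intensities are
divided by a per-file scale so values fit the TIFF float range; the
sidecar `<file>.tif.json` holds `shape_zyx`, `n_channels`,
`spacing_zyx_nm`, `channels` (role labels) and `intensity_scale`.

## Spot tables (`spots_rna.csv`, `spots_protein.csv`)

`spot_id, channel, z_nm, y_nm, x_nm, amplitude, sigma_z, sigma_y,
sigma_x, background, fit_ok` — one row per fitted focus; only
`fit_ok = TRUE` rows feed downstream stages.

## Granule summary (`granules.csv`)

`granule_id, volume_voxels, n_surface, touches_border, centroid_z_nm,
centroid_y_nm, centroid_x_nm`.

## Signed-distance records (`distances.csv`)

`spot_id, nearest_granule_id, signed_distance_nm, excluded,
exclusion_reason` — distance negative inside a granule;
`exclusion_reason` is `none`, `border_granule` or `no_granules`.

## Distance histogram (`histogram.json`)

`edges` (nm, 25 nm wide, aligned at 0), `freq` (relative frequencies,
sum 1), `kde_x`/`kde_y` (Gaussian KDE, Scott bandwidth), `n_used`,
`n_excluded`.

## Translation calls (`calls.csv`)

`rna_spot_id, protein_spot_id, pair_distance_nm, translating` —
`protein_spot_id` empty when unmatched.

## FRAP curves (`write_frap_csv` / `read_frap_csv`)

`t_seconds, intensity, is_prebleach`.

## Run metadata

`summary.json` (counts and the translating fraction), `config.yaml`
(the full configuration), `provenance.json` (`config_md5`, `seed`,
package name and version; no timestamps, so identical runs are
byte-identical).
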