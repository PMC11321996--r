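spacing <- c(150, 42.5, 42.5)
psf_nm <- c(300, 100, 100)
sigma_vox <- psf_nm / spacing

# render n well-separated PSF-shaped spots into a clean volume
render_separated <- function(n, shape = c(16, 160, 160), amp = 200,
                             seed = 1, noise_sd = 0) {
  set.seed(seed)
  ext <- shape * spacing
  pos <- separated_positions(n, ext, min_sep = 1000)
  arr <- array(0, shape)
  for (i in seq_len(n)) {
    arr <- suntagr:::add_spot(arr, pos[i, ], amp, psf_nm, spacing)
  }
  if (noise_sd > 0) arr <- arr + rnorm(length(arr), 0, noise_sd)
  list(arr = arr, pos = pos)
}

test_that("pre-detection counts are zero on blanks and non-increasing", {
  blank <- array(0, c(8, 32, 32))
  curve <- predetect(blank, threshold_grid = seq(0.1, 1, length.out = 12))
  expect_true(all(curve$counts == 0))
  f <- render_separated(30, seed = 2, noise_sd = 1)
  curve <- predetect(f$arr, psf_sigma_vox = sigma_vox)
  expect_true(all(diff(curve$counts) <= 0))
})

test_that("counts plateau at the true spot number on clean fields", {
  f <- render_separated(50, seed = 3, noise_sd = 0.5)
  curve <- predetect(f$arr, psf_sigma_vox = sigma_vox)
  thr <- select_threshold(curve)
  n_at <- curve$counts[max(which(curve$thresholds <= thr))]
  expect_lt(abs(n_at - 50) / 50, 0.05)
})

test_that("plateau selection picks the left edge of the longest flat run", {
  # counts drop exponentially, flatten at ~50, then decay again: the rule
  # must return the first threshold of the {52,50,50,49} run
  thresholds <- 2^(0:7)
  counts <- c(5000L, 800L, 52L, 50L, 50L, 49L, 12L, 2L)
  curve <- structure(list(thresholds = thresholds, counts = counts),
                     class = "ThresholdCurve")
  expect_equal(select_threshold(curve, plateau_tol = 0.2, min_run = 4),
               thresholds[3])
  # a strictly exponential curve has no flat run
  curve2 <- structure(list(thresholds = thresholds,
                           counts = as.integer(round(1e5 * 0.3^(0:7)))),
                      class = "ThresholdCurve")
  expect_error(select_threshold(curve2), "plateau")
})

test_that("threshold selection is equivariant under intensity rescaling", {
  f <- render_separated(25, seed = 4, noise_sd = 0.5)
  t1 <- select_threshold(predetect(f$arr, psf_sigma_vox = sigma_vox))
  t5 <- select_threshold(predetect(5 * f$arr, psf_sigma_vox = sigma_vox))
  expect_equal(t5 / t1, 5, tolerance = 1e-9)
})

test_that("Gaussian fits recover sub-voxel centroids", {
  # single clean focus at an exact position
  arr <- array(0, c(16, 96, 96))
  arr <- suntagr:::add_spot(arr, c(1500, 2125, 2125), 200, psf_nm, spacing)
  sp <- fit_spots(arr, 1, spacing, psf_sigma_vox = sigma_vox)
  expect_equal(nrow(sp), 1)
  expect_true(sp$fit_ok)
  expect_lt(abs(sp$z_nm - 1500), 0.25 * spacing[1])
  expect_lt(abs(sp$y_nm - 2125), 0.25 * spacing[2])
  expect_lt(abs(sp$x_nm - 2125), 0.25 * spacing[3])
  # two spots 1.5 um apart resolve into two accurate fits
  arr2 <- array(0, c(16, 96, 96))
  p1 <- c(1200, 1500, 1500); p2 <- c(1200, 1500, 3000)
  arr2 <- suntagr:::add_spot(arr2, p1, 200, psf_nm, spacing)
  arr2 <- suntagr:::add_spot(arr2, p2, 200, psf_nm, spacing)
  sp2 <- fit_spots(arr2, 1, spacing, psf_sigma_vox = sigma_vox)
  sp2 <- sp2[sp2$fit_ok, ]
  expect_equal(nrow(sp2), 2)
  for (p in list(p1, p2)) {
    d <- sqrt((sp2$z_nm - p[1])^2 + (sp2$y_nm - p[2])^2 +
              (sp2$x_nm - p[3])^2)
    i <- which.min(d)
    expect_lt(abs(sp2$z_nm[i] - p[1]), 0.25 * spacing[1])
    expect_lt(abs(sp2$y_nm[i] - p[2]), 0.25 * spacing[2])
    expect_lt(abs(sp2$x_nm[i] - p[3]), 0.25 * spacing[3])
  }
})

test_that("fitted amplitude is linear in source brightness", {
  amps <- vapply(c(1, 10), function(k) {
    arr <- array(0, c(12, 64, 64))
    arr <- suntagr:::add_spot(arr, c(900, 1360, 1360), 50 * k, psf_nm,
                              spacing)
    sp <- fit_spots(arr, 0.1, spacing, psf_sigma_vox = sigma_vox)
    sp$amplitude[which.max(sp$amplitude)]
  }, 0)
  expect_equal(amps[2] / amps[1], 10, tolerance = 0.01)
})

test_that("detection and fitting achieve high recall/precision at SNR >= 5", {
  f <- render_separated(40, seed = 6, noise_sd = 2)
  arr <- array(rpois(length(f$arr), pmax(f$arr, 0)), dim(f$arr)) +
    rnorm(length(f$arr), 0, 2)
  thr <- select_threshold(predetect(arr, psf_sigma_vox = sigma_vox))
  sp <- fit_spots(arr, thr, spacing, psf_sigma_vox = sigma_vox)
  sp <- sp[sp$fit_ok, ]
  d2 <- outer(sp$z_nm, f$pos[, 1], "-")^2 +
    outer(sp$y_nm, f$pos[, 2], "-")^2 + outer(sp$x_nm, f$pos[, 3], "-")^2
  hit <- sqrt(apply(d2, 2, min)) < 300   # truth matched by a detection
  tp <- sqrt(apply(d2, 1, min)) < 300    # detection near a truth
  expect_gte(mean(hit), 0.95)
  expect_gte(mean(tp), 0.95)
  # centroid accuracy: RMSE under 0.3 voxel per axis
  nn <- apply(d2, 2, which.min)
  ok <- hit
  rmse_z <- sqrt(mean((sp$z_nm[nn[ok]] - f$pos[ok, 1])^2))
  rmse_y <- sqrt(mean((sp$y_nm[nn[ok]] - f$pos[ok, 2])^2))
  rmse_x <- sqrt(mean((sp$x_nm[nn[ok]] - f$pos[ok, 3])^2))
  expect_lt(rmse_z, 0.3 * spacing[1])
  expect_lt(rmse_y, 0.3 * spacing[2])
  expect_lt(rmse_x, 0.3 * spacing[3])
})

make_frame <- function(pos) {
  data.frame(spot_id = seq_len(nrow(pos)), z_nm = pos[, 1],
             y_nm = pos[, 2], x_nm = pos[, 3])
}

test_that("linker follows stationary and gapped spots", {
  p <- matrix(c(1000, 2000, 3000), 1)
  frames <- replicate(40, make_frame(p), simplify = FALSE)
  tracks <- link_tracks(frames)
  expect_equal(length(tracks), 1)
  expect_equal(nrow(tracks[[1]]), 40)
  expect_equal(attr(tracks[[1]], "gaps"), 0L)
  # spot missing in one frame: a single track with one closed gap
  frames[[20]] <- make_frame(matrix(numeric(), 0, 3))
  tracks <- link_tracks(frames)
  expect_equal(length(tracks), 1)
  expect_equal(nrow(tracks[[1]]), 39)
  expect_equal(attr(tracks[[1]], "gaps"), 1L)
})

test_that("mutual-NN linking does not swap converging tracks", {
  # two spots approach to within max_disp then separate; mutual nearest
  # neighbours keep each on its own (nearer) continuation
  t_seq <- seq(0, 10)
  ya <- 1000 + 100 * abs(t_seq - 5)   # V shape, min separation 400 nm
  yb <- 600 - 100 * abs(t_seq - 5) + 2600
  frames <- lapply(seq_along(t_seq), function(i) {
    make_frame(rbind(c(1000, ya[i], 1000), c(1000, yb[i], 1000)))
  })
  tracks <- link_tracks(frames, max_disp = 1000)
  expect_equal(length(tracks), 2)
  for (tr in tracks) {
    expect_equal(nrow(tr), length(t_seq))
    expect_true(all(abs(diff(tr$y_nm)) <= 200))  # no jump across lanes
  }
})

test_that("track-length filter is strict", {
  mk <- function(n) {
    frames <- replicate(n, make_frame(matrix(c(0, 0, 0), 1)),
                        simplify = FALSE)
    link_tracks(frames)[[1]]
  }
  tracks <- list(mk(40), mk(30), mk(10))
  kept <- filter_long_tracks(tracks, min_frames = 30)
  expect_equal(vapply(kept, nrow, 0L), 40L)
})
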