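spacing <- c(150, 42.5, 42.5)

make_spots <- function(pos) {
  pos <- matrix(pos, ncol = 3)
  data.frame(spot_id = seq_len(nrow(pos)), z_nm = pos[, 1],
             y_nm = pos[, 2], x_nm = pos[, 3])
}

test_that("sphere geometry: center and radial spots recover analytic distances", {
  shape <- c(16, 64, 64)
  center <- shape * spacing / 2
  lm <- label_and_classify(sphere_mask(shape, spacing, center, 300))
  half_diag <- sqrt(sum((spacing / 2)^2))  # ~82 nm
  rec <- signed_distances(make_spots(center), lm, spacing)
  # the sphere's polar cap lies entirely in one voxel plane at 150 nm
  # axial spacing, so its surface-voxel centers sit slightly deeper than
  # half a voxel diagonal below the true surface; allow that excess
  expect_lt(abs(rec$signed_distance_nm - (-300)), 1.1 * half_diag)
  # spots placed radially outside along +x at known clearances
  ds <- c(100, 250, 500, 750)
  pos <- t(vapply(ds, function(s) center + c(0, 0, 300 + s), numeric(3)))
  rec <- signed_distances(make_spots(pos), lm, spacing)
  expect_true(all(rec$signed_distance_nm > 0))
  expect_true(all(abs(rec$signed_distance_nm - ds) < half_diag))
})

test_that("signed distances equal the exhaustive brute-force oracle", {
  set.seed(11)
  for (rep in 1:4) {
    mask <- random_mask(c(12, 16, 16), n_obj = 3)
    lm <- label_and_classify(mask)
    ext <- dim(mask) * spacing
    pos <- cbind(runif(50, 0, ext[1]), runif(50, 0, ext[2]),
                 runif(50, 0, ext[3]))
    rec <- signed_distances(make_spots(pos), lm, spacing)
    for (i in seq_len(nrow(pos))) {
      o <- oracle_signed_distance(pos[i, ], lm, spacing)
      expect_identical(rec$signed_distance_nm[i], o$distance)
      expect_identical(rec$nearest_granule_id[i], o$granule_id)
    }
  }
})

test_that("no-granule input yields excluded infinite records", {
  lm <- label_and_classify(array(FALSE, c(4, 8, 8)))
  rec <- signed_distances(make_spots(c(100, 100, 100)), lm, spacing)
  expect_true(all(rec$excluded))
  expect_true(all(is.infinite(rec$signed_distance_nm)))
  expect_true(all(is.na(rec$nearest_granule_id)))
})

test_that("border-granule exclusion matches an independent recount", {
  shape <- c(12, 48, 48)
  # one interior sphere, one touching the z border
  m <- sphere_mask(shape, spacing, c(900, 800, 800), 250) |
    sphere_mask(shape, spacing, c(80, 1400, 1400), 250)
  lm <- label_and_classify(m)
  expect_equal(sum(lm$granules$touches_border), 1L)
  set.seed(3)
  ext <- shape * spacing
  pos <- cbind(runif(100, 0, ext[1]), runif(100, 0, ext[2]),
               runif(100, 0, ext[3]))
  rec <- apply_exclusions(signed_distances(make_spots(pos), lm, spacing), lm)
  expect_equal(nrow(rec), 100)  # conservation
  border_id <- lm$granules$granule_id[lm$granules$touches_border]
  expect_equal(sum(rec$excluded),
               sum(rec$nearest_granule_id == border_id))
  expect_true(all(rec$exclusion_reason[rec$excluded] == "border_granule"))
  # all-interior case: nothing excluded
  lm2 <- label_and_classify(sphere_mask(shape, spacing,
                                        c(900, 800, 800), 250))
  rec2 <- apply_exclusions(signed_distances(make_spots(pos), lm2, spacing),
                           lm2)
  expect_equal(sum(rec2$excluded), 0)
})

test_that("histogram is a relative-frequency histogram on 25 nm bins", {
  rec <- data.frame(spot_id = 1:40,
                    signed_distance_nm = rep(-100, 40),
                    excluded = FALSE)
  h <- histogram_with_kde(rec)
  expect_equal(sum(h$freq), 1, tolerance = 1e-9)
  expect_equal(h$freq[1], 1)  # single bin [-100, -75)
  expect_equal(h$edges[1], -100)
  expect_equal(diff(h$edges)[1], 25)
  # mixed sample still sums to one and uses only non-excluded records
  set.seed(2)
  rec2 <- data.frame(spot_id = 1:500,
                     signed_distance_nm = rnorm(500, 0, 80),
                     excluded = rep(c(FALSE, TRUE), c(400, 100)))
  h2 <- histogram_with_kde(rec2)
  expect_equal(sum(h2$freq), 1, tolerance = 1e-9)
  expect_equal(h2$n_used, 400)
  expect_equal(h2$n_excluded, 100)
  expect_error(histogram_with_kde(
    data.frame(spot_id = 1, signed_distance_nm = 1, excluded = TRUE)),
    "no non-excluded")
})

test_that("surface-shell placement puts the histogram mode at the border", {
  cfg <- phantom_config(seed = 31, n_rna_spots = 1500, n_granules = 12,
                        translating_fraction = 0,
                        placement_law = placement_surface_shell(0, 40),
                        shape_zyx = c(20, 160, 160))
  ph <- generate_phantom(cfg, render = FALSE)
  rec <- data.frame(spot_id = ph$truth$rna$spot_id,
                    signed_distance_nm = ph$truth$rna$true_signed_distance_nm,
                    excluded = FALSE)
  h <- histogram_with_kde(rec)
  mode_bin <- which.max(h$freq)
  mode_center <- (h$edges[mode_bin] + h$edges[mode_bin + 1]) / 2
  expect_lte(abs(mode_center), 25 + 12.5)
})

test_that("rotation control is an involution with the center fixed", {
  shape <- c(16, 64, 64)
  ext <- shape * spacing
  ctr <- make_spots(c(ext[1] / 3, ext[2] / 2, ext[3] / 2))
  rot <- rotation_control(ctr, shape, spacing)
  expect_equal(rot$y_nm, ctr$y_nm)
  expect_equal(rot$x_nm, ctr$x_nm)
  expect_equal(rot$z_nm, ctr$z_nm)  # z untouched
  set.seed(5)
  sp <- make_spots(cbind(runif(50, 0, ext[1]), runif(50, 0, ext[2]),
                         runif(50, 0, ext[3])))
  twice <- rotation_control(rotation_control(sp, shape, spacing),
                            shape, spacing)
  expect_equal(twice, sp)
})

test_that("rotation destroys surface enrichment down to the uniform level", {
  # a well-covered germplasm-like crop: dense granule field so that
  # per-granule spot clusters are small and binomial error applies
  cfg <- phantom_config(seed = 17, n_rna_spots = 2000, n_granules = 150,
                        translating_fraction = 0,
                        placement_law = placement_surface_shell(0, 30),
                        shape_zyx = c(20, 512, 512))
  ph <- generate_phantom(cfg, render = FALSE)
  tr <- ph$truth
  surface_frac <- function(spots) {
    d <- sphere_signed_distance(
      as.matrix(spots[, c("z_nm", "y_nm", "x_nm")]), tr$granules)$distance
    mean(abs(d) <= 50)
  }
  f_orig <- surface_frac(tr$rna)
  rot <- rotation_control(tr$rna, cfg$shape_zyx, spacing)
  f_rot <- surface_frac(rot)
  unif <- uniform_random_control(50000, cfg$shape_zyx, spacing, seed = 99)
  f_unif <- surface_frac(unif)
  sd_rot <- sqrt(f_unif * (1 - f_unif) / nrow(rot))
  expect_gt(f_orig, 0.5)                      # strong enrichment before
  expect_lt(abs(f_rot - f_unif), 2 * sd_rot + 1e-12)  # gone after
})

test_that("uniform control stays in bounds and fills granules by volume", {
  shape <- c(16, 96, 96)
  ext <- shape * spacing
  pts <- uniform_random_control(30000, shape, spacing, seed = 4)
  expect_equal(nrow(pts), 30000)
  expect_true(all(pts$z_nm >= 0 & pts$z_nm < ext[1]))
  expect_true(all(pts$y_nm >= 0 & pts$y_nm < ext[2]))
  expect_true(all(pts$x_nm >= 0 & pts$x_nm < ext[3]))
  # reproducible under the same seed
  expect_identical(pts, uniform_random_control(30000, shape, spacing, 4))
  granules <- data.frame(z_nm = c(1100, 1300), y_nm = c(1000, 2800),
                         x_nm = c(1500, 2500), radius_nm = c(300, 350))
  d <- sphere_signed_distance(as.matrix(pts[, 2:4]), granules)$distance
  p_in <- mean(d < 0)
  p_true <- sum(4 / 3 * pi * granules$radius_nm^3) / prod(ext)
  expect_lt(abs(p_in - p_true),
            3 * sqrt(p_true * (1 - p_true) / nrow(pts)))
})

test_that("whole-voxel translation leaves signed distances unchanged", {
  set.seed(9)
  base <- random_mask(c(10, 14, 14), 2)
  mask <- array(FALSE, c(14, 20, 20))
  mask[3:12, 4:17, 4:17] <- base
  shifted <- array(FALSE, c(14, 20, 20))
  shifted[4:13, 6:19, 5:18] <- base  # shift by (1, 2, 1) voxels
  lm_a <- label_and_classify(mask)
  lm_b <- label_and_classify(shifted)
  ext <- c(14, 20, 20) * spacing
  pos <- cbind(runif(40, 0.3, 0.7) * ext[1], runif(40, 0.3, 0.7) * ext[2],
               runif(40, 0.3, 0.7) * ext[3])
  off <- c(1, 2, 1) * spacing
  rec_a <- signed_distances(make_spots(pos), lm_a, spacing)
  rec_b <- signed_distances(make_spots(sweep(pos, 2, -off)), lm_b, spacing)
  expect_equal(rec_b$signed_distance_nm, rec_a$signed_distance_nm)
})

test_that("moving a spot radially outward increases its signed distance", {
  shape <- c(16, 64, 64)
  center <- shape * spacing / 2
  lm <- label_and_classify(sphere_mask(shape, spacing, center, 300))
  ds <- seq(0, 800, by = 100)
  pos <- t(vapply(ds, function(s) center + c(0, 0, 300 + s), numeric(3)))
  rec <- signed_distances(make_spots(pos), lm, spacing)
  expect_true(all(diff(rec$signed_distance_nm) > 0))
})
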