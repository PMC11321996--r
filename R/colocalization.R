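#' Pixel-level Pearson co-localization of two channels
#'
#' Optionally subtracts a slice-wise morphological-opening background
#' (disc of \code{background_radius} voxels, applied per z-slice), finds
#' an automatic threshold per channel, and computes the Pearson
#' correlation of the two channels over the union of above-threshold
#' voxels. Identical channels give exactly 1.
#'
#' @param img_a,img_b 3D arrays of equal shape
#' @param background_method \code{"opening"} or \code{"none"}
#' @param background_radius opening disc radius in voxels
#' @param threshold_method \code{"otsu"} or \code{"isodata"} (global
#'   automatic thresholds) or \code{"none"} (all voxels)
#' @return list of class \code{PccResult}: \code{pcc},
#'   \code{n_voxels_used}, \code{background_subtracted},
#'   \code{threshold_method}
#' @export
pearson_coloc <- function(img_a, img_b,
                          background_method = c("none", "opening"),
                          background_radius = 7L,
                          threshold_method = c("otsu", "isodata", "none")) {
  background_method <- match.arg(background_method)
  threshold_method <- match.arg(threshold_method)
  stopifnot(all(dim(img_a) == dim(img_b)))
  if (background_method == "opening") {
    img_a <- subtract_background_opening(img_a, background_radius)
    img_b <- subtract_background_opening(img_b, background_radius)
  }
  use <- if (threshold_method == "none") {
    array(TRUE, dim(img_a))
  } else {
    thr <- switch(threshold_method, otsu = otsu_threshold,
                  isodata = isodata_threshold)
    img_a > thr(img_a) | img_b > thr(img_b)
  }
  a <- img_a[use]; b <- img_b[use]
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: a channel is constant over the ",
         "analysis voxel set")
  }
  structure(list(pcc = stats::cor(a, b), n_voxels_used = length(a),
                 background_subtracted = background_method != "none",
                 threshold_method = threshold_method),
            class = "PccResult")
}

# slice-wise grayscale opening (EBImage disc brush) as a background
# estimate; the opened image is subtracted, clamping at zero
subtract_background_opening <- function(arr, radius) {
  size <- 2L * as.integer(radius) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  d <- dim(arr)
  bg <- array(0, d)
  for (z in seq_len(d[1])) {
    bg[z, , ] <- as.array(EBImage::opening(EBImage::Image(arr[z, , ]), brush))
  }
  pmax(arr - bg, 0)
}

#' Average randomly sampled granule-centered sub-volumes
#'
#' Samples \code{n} granule centers (without replacement, seeded) whose
#' surrounding box lies fully inside the volume, extracts the box around
#' each center per channel and returns the voxel-wise mean. Averaging
#' suppresses uncorrelated noise roughly by sqrt(n) and reveals the mean
#' radial arrangement of channels around granules.
#'
#' @param stack \code{\link{image_stack}}
#' @param centers_nm matrix/data.frame of granule centers (z_nm, y_nm,
#'   x_nm)
#' @param n granules to average
#' @param box_vox odd box size in voxels (z, y, x)
#' @param seed integer seed
#' @return list of class \code{AveragedGranuleImage}: \code{mean} (4D
#'   array box x channels), \code{n_granules_averaged}, \code{box_vox}
#' @export
average_granules <- function(stack, centers_nm, n = 40L,
                             box_vox = c(9L, 21L, 21L), seed = 1L) {
  stopifnot(inherits(stack, "ImageStack"), all(box_vox %% 2L == 1L))
  centers_nm <- as.matrix(as.data.frame(centers_nm)[, 1:3])
  d <- dim(stack$data)[1:3]
  half <- (as.integer(box_vox) - 1L) %/% 2L
  vox <- pos_to_voxel(centers_nm, stack$spacing, d)
  eligible <- which(vox[, 1] - half[1] >= 1L & vox[, 1] + half[1] <= d[1] &
                    vox[, 2] - half[2] >= 1L & vox[, 2] + half[2] <= d[2] &
                    vox[, 3] - half[3] >= 1L & vox[, 3] + half[3] <= d[3])
  if (length(eligible) == 0L) stop("no granule fits the box margin")
  set.seed(seed)
  if (length(eligible) < n) {
    warning("only ", length(eligible), " eligible granules; using all")
    picked <- eligible
  } else {
    picked <- sample(eligible, n)
  }
  nc <- dim(stack$data)[4]
  acc <- array(0, c(box_vox, nc))
  for (g in picked) {
    zr <- (vox[g, 1] - half[1]):(vox[g, 1] + half[1])
    yr <- (vox[g, 2] - half[2]):(vox[g, 2] + half[2])
    xr <- (vox[g, 3] - half[3]):(vox[g, 3] + half[3])
    acc <- acc + stack$data[zr, yr, xr, , drop = FALSE]
  }
  structure(list(mean = acc / length(picked),
                 n_granules_averaged = length(picked),
                 box_vox = as.integer(box_vox),
                 channels = stack$channels),
            class = "AveragedGranuleImage")
}

# trilinear interpolation of a 3D array at fractional voxel-index
# coordinates (voxel-center convention; clamped at the borders)
trilinear <- function(arr, fz, fy, fx) {
  d <- dim(arr)
  cl <- function(f, n) pmin(pmax(f, 1), n)
  fz <- cl(fz, d[1]); fy <- cl(fy, d[2]); fx <- cl(fx, d[3])
  z0 <- pmin(floor(fz), d[1] - 1L); z1 <- z0 + 1
  y0 <- pmin(floor(fy), d[2] - 1L); y1 <- y0 + 1
  x0 <- pmin(floor(fx), d[3] - 1L); x1 <- x0 + 1
  if (d[1] == 1L) { z0 <- z1 <- rep(1, length(fz)) }
  wz <- fz - z0; wy <- fy - y0; wx <- fx - x0
  at <- function(z, y, x) arr[cbind(z, y, x)]
  (1 - wz) * ((1 - wy) * ((1 - wx) * at(z0, y0, x0) + wx * at(z0, y0, x1)) +
              wy * ((1 - wx) * at(z0, y1, x0) + wx * at(z0, y1, x1))) +
    wz * ((1 - wy) * ((1 - wx) * at(z1, y0, x0) + wx * at(z1, y0, x1)) +
          wy * ((1 - wx) * at(z1, y1, x0) + wx * at(z1, y1, x1)))
}

#' Intensity profile along a 3D line segment
#'
#' Samples one or more channels at evenly spaced points between two
#' physical endpoints by trilinear interpolation.
#' @param stack \code{\link{image_stack}}
#' @param p0_nm,p1_nm endpoints, length-3 nm (z, y, x); must differ
#' @param channels channel labels (default all)
#' @param n_samples number of sample points
#' @return data.frame: distance_nm, channel, intensity
#' @export
line_profile <- function(stack, p0_nm, p1_nm, channels = NULL,
                         n_samples = 100L) {
  stopifnot(inherits(stack, "ImageStack"), length(p0_nm) == 3L,
            length(p1_nm) == 3L)
  if (all(p0_nm == p1_nm)) stop("degenerate segment: endpoints coincide")
  ext <- physical_extent(stack)
  if (any(p0_nm < 0) || any(p0_nm > ext) || any(p1_nm < 0) ||
      any(p1_nm > ext)) {
    stop("endpoints must lie inside the physical volume")
  }
  if (is.null(channels)) channels <- stack$channels
  tt <- seq(0, 1, length.out = n_samples)
  pts <- cbind(p0_nm[1] + tt * (p1_nm[1] - p0_nm[1]),
               p0_nm[2] + tt * (p1_nm[2] - p0_nm[2]),
               p0_nm[3] + tt * (p1_nm[3] - p0_nm[3]))
  dist <- tt * sqrt(sum((p1_nm - p0_nm)^2))
  fz <- pts[, 1] / stack$spacing[1] + 0.5
  fy <- pts[, 2] / stack$spacing[2] + 0.5
  fx <- pts[, 3] / stack$spacing[3] + 0.5
  do.call(rbind, lapply(channels, function(ch) {
    data.frame(distance_nm = dist, channel = ch,
               intensity = trilinear(get_channel(stack, ch), fz, fy, fx))
  }))
}
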