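# Conventions used throughout the package:
#  * volumes are 3D arrays indexed [z, y, x] (1-based R indices)
#  * voxel spacing is a length-3 numeric c(z, y, x) in nm
#  * the physical position of voxel i along an axis is (i - 0.5) * spacing
#    (voxel-center convention); the image occupies [0, n * spacing) per axis

#' Physical coordinates of voxel centers along one axis
#' @param n number of voxels
#' @param spacing nm per voxel
#' @return numeric vector of nm positions
#' @keywords internal
voxel_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Voxel index containing a physical coordinate
#'
#' Coordinates in [0, n*spacing) map to 1..n; values are clamped to the
#' valid range so spots a hair outside (floating point) stay in-volume.
#' @keywords internal
containing_voxel <- function(x_nm, spacing, n) {
  pmin(pmax(floor(x_nm / spacing) + 1L, 1L), n)
}

#' Convert a physical zyx position matrix to voxel indices
#' @param pos matrix with columns z_nm, y_nm, x_nm
#' @keywords internal
pos_to_voxel <- function(pos, spacing, shape) {
  cbind(containing_voxel(pos[, 1], spacing[1], shape[1]),
        containing_voxel(pos[, 2], spacing[2], shape[2]),
        containing_voxel(pos[, 3], spacing[3], shape[3]))
}

gaussian_kernel_1d <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve one axis of a 3D array with a 1D kernel (zero padding at
# edges).  Implemented as a banded-matrix multiply on the matricised
# array; for the volume sizes used here this is faster in R than an
# explicit loop and exactly linear, which the rendering tests rely on.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(arr)
  K <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    idx <- which(seq_len(n) + off >= 1 & seq_len(n) + off <= n)
    K[cbind(idx, idx + off)] <- kernel[off + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = n)
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' Separable anisotropic Gaussian blur of a 3D volume
#'
#' With \code{normalize = TRUE} the kernel is renormalized at the image
#' borders (division by the blur of a ones-volume), so responses near
#' the volume edges are not attenuated by the zero padding; rendering
#' uses the plain zero-padded blur (photons leaving the volume are
#' lost), detection filters use the normalized one.
#' @param arr 3D array (z, y, x)
#' @param sigma_vox length-3 sigma in voxels (z, y, x)
#' @param normalize renormalize at the borders
#' @keywords internal
gauss_blur_3d <- function(arr, sigma_vox, normalize = FALSE) {
  out <- arr
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      out <- convolve_axis(out, gaussian_kernel_1d(sigma_vox[ax]), ax)
    }
  }
  if (normalize) {
    ones <- array(1, dim(arr))
    for (ax in 1:3) {
      if (sigma_vox[ax] > 0) {
        ones <- convolve_axis(ones, gaussian_kernel_1d(sigma_vox[ax]), ax)
      }
    }
    out <- out / ones
  }
  out
}

# Shift a 3D array by integer offsets, filling vacated voxels with `fill`.
shift_3d <- function(arr, dz, dy, dx, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  src_z <- seq_len(d[1]) - dz; src_y <- seq_len(d[2]) - dy; src_x <- seq_len(d[3]) - dx
  ok_z <- src_z >= 1 & src_z <= d[1]
  ok_y <- src_y >= 1 & src_y <= d[2]
  ok_x <- src_x >= 1 & src_x <= d[3]
  out[which(ok_z), which(ok_y), which(ok_x)] <-
    arr[src_z[ok_z], src_y[ok_y], src_x[ok_x], drop = FALSE]
  out
}

#' Local maxima of a 3D volume (26-connectivity, strict)
#'
#' A voxel is a local maximum when its value is strictly greater than
#' all 26 neighbours. With \code{exclude_border = TRUE} (the default for
#' detection) maxima on the outermost voxel shell are suppressed: the
#' border-renormalized band-pass filter extrapolates beyond the volume
#' and can turn the flank of a near-border object into a spurious
#' border-plane maximum.
#' @return logical array of the same shape
#' @keywords internal
local_maxima_3d <- function(arr, exclude_border = TRUE) {
  is_max <- array(TRUE, dim(arr))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    # value plateaus (exact ties between adjacent voxels) resolve to the
    # lexicographically first voxel: ties with later voxels pass with
    # >=, ties with earlier voxels fail the strict >
    off <- c(dz, dy, dx)
    later_neighbor <- off[which(off != 0)[1]] < 0
    nb <- shift_3d(arr, dz, dy, dx, fill = -Inf)
    is_max <- is_max & if (later_neighbor) arr >= nb else arr > nb
  }
  if (exclude_border) {
    d <- dim(arr)
    if (d[1] > 2L) is_max[c(1L, d[1]), , ] <- FALSE
    if (d[2] > 2L) is_max[, c(1L, d[2]), ] <- FALSE
    if (d[3] > 2L) is_max[, , c(1L, d[3])] <- FALSE
  }
  is_max
}

#' Laplacian-of-Gaussian band-pass filter for blob detection
#'
#' Gaussian blur at the PSF scale followed by a negated 6-neighbour
#' discrete Laplacian, so diffraction-limited spots become positive
#' peaks. The filter is linear: scaling the input scales the response.
#' @param arr 3D array (z, y, x)
#' @param sigma_vox blur sigma in voxels (z, y, x)
#' @return filtered array, same shape
#' @export
log_filter <- function(arr, sigma_vox) {
  g <- gauss_blur_3d(arr, sigma_vox, normalize = TRUE)
  lap <- array(0, dim(arr))
  for (ax in 1:3) {
    off <- c(0L, 0L, 0L)
    off[ax] <- 1L
    lap <- lap +
      shift_3d(g, off[1], off[2], off[3], fill = 0) +
      shift_3d(g, -off[1], -off[2], -off[3], fill = 0) - 2 * g
  }
  -lap
}

#' Global Otsu threshold of a numeric volume
#'
#' Thin wrapper around \code{EBImage::otsu} applied to the pooled voxel
#' intensities (one global threshold, not per-slice).
#' @param arr numeric array
#' @return scalar threshold
#' @export
otsu_threshold <- function(arr) {
  v <- as.numeric(arr)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)), range = rng)
}

#' Isodata (intermeans) automatic threshold
#'
#' Classic iterative scheme: the threshold is repeatedly set to the
#' midpoint of the mean intensities above and below it until it
#' stabilizes. An alternative automatic threshold to Otsu's, used to
#' check that co-localization statistics do not depend on the choice.
#' @param arr numeric array
#' @return scalar threshold
#' @export
isodata_threshold <- function(arr) {
  v <- as.numeric(arr)
  t <- mean(v)
  for (i in seq_len(100L)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 1e-10 * max(abs(t), 1)) break
    t <- t_new
  }
  t
}
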