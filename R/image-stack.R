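#' Multi-channel 3D image stack
#'
#' Container for a multi-channel 3D fluorescence volume with anisotropic
#' voxel spacing. Voxel data are stored as a 4D array indexed
#' \code{[z, y, x, channel]}; spacing is nm per voxel in z, y, x order.
#' Channel roles (e.g. \code{"granule"}, \code{"rna"}, \code{"protein"})
#' are carried as dimnames of the channel axis.
#'
#' @param data 4D numeric array [z, y, x, channel] (a 3D array is treated
#'   as a single channel)
#' @param spacing_zyx nm per voxel, length 3 (z, y, x)
#' @param channels character vector of channel role labels
#' @return an object of class \code{ImageStack}
#' @export
image_stack <- function(data, spacing_zyx, channels = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L, length(spacing_zyx) == 3L,
            all(spacing_zyx > 0))
  nc <- dim(data)[4]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  stopifnot(length(channels) == nc)
  structure(list(data = data, spacing = as.numeric(spacing_zyx),
                 channels = as.character(channels)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d x %d x %d voxels (z,y,x), %d channel(s)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing (nm): z=%g y=%g x=%g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of an ImageStack as a 3D array
#' @param stack ImageStack
#' @param channel channel role label or index
#' @return 3D array (z, y, x)
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.character(channel)) {
    i <- match(channel, stack$channels)
    if (is.na(i)) stop("unknown channel: ", channel)
  } else i <- channel
  stack$data[, , , i]
}

#' Physical shape of an ImageStack
#' @return length-3 numeric, extent in nm per axis (z, y, x)
#' @export
physical_extent <- function(stack) {
  dim(stack$data)[1:3] * stack$spacing
}

#' Write an ImageStack to a multi-page TIFF with a JSON sidecar
#'
#' Pages are z-slices, channel-major (all z of channel 1, then channel 2,
#' ...). Intensities are stored as 32-bit float after division by a
#' per-file scale factor (TIFF float data must lie in [0, 1]); the scale,
#' spacing, shape and channel roles go into \code{<path>.json} so the
#' stack round-trips exactly up to float precision.
#' @param stack ImageStack
#' @param path output .tif path
#' @return \code{path}, invisibly
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- vector("list", d[4] * d[1])
  k <- 1L
  for (ch in seq_len(d[4])) for (z in seq_len(d[1])) {
    pages[[k]] <- stack$data[z, , , ch] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(shape_zyx = d[1:3], n_channels = d[4],
               spacing_zyx_nm = stack$spacing, channels = stack$channels,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ImageStack written by \code{write_image_stack}
#' @param path .tif path (expects \code{<path>.json} sidecar)
#' @return ImageStack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$shape_zyx)
  nc <- as.integer(meta$n_channels)
  arr <- array(0, c(d, nc))
  k <- 1L
  for (ch in seq_len(nc)) for (z in seq_len(d[1])) {
    arr[z, , , ch] <- pages[[k]] * meta$intensity_scale
    k <- k + 1L
  }
  image_stack(arr, meta$spacing_zyx_nm, meta$channels)
}

#' Write / read a FRAP curve as CSV
#'
#' Columns: \code{t_seconds}, \code{intensity}, \code{is_prebleach}.
#' @param curve FrapCurve (see \code{\link{simulate_frap_curve}})
#' @param path CSV path
#' @return \code{path} / FrapCurve
#' @export
write_frap_csv <- function(curve, path) {
  df <- data.frame(t_seconds = curve$t, intensity = curve$intensity,
                   is_prebleach = seq_along(curve$t) <= curve$prebleach_frames)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_seconds", "intensity", "is_prebleach") %in% names(df)))
  pre <- sum(df$is_prebleach)
  frap_curve(t = df$t_seconds, intensity = df$intensity,
             bleach_index = pre + 1L, prebleach_frames = pre)
}
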