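#' Signed minimum distance of spots to the nearest granule surface
#'
#' For every spot, the minimum anisotropic Euclidean distance (nm) from
#' its centroid to any surface-voxel center of the label map, signed
#' negative when the spot's containing voxel belongs to a granule and
#' positive otherwise. The nearest granule is the owner of the minimizing
#' surface voxel; exact distance ties are broken towards the lower
#' granule id. Distances are computed by (chunked) exhaustive search over
#' all surface-voxel centers, i.e. the implementation is the brute-force
#' definition itself.
#'
#' @param spots data.frame with spot_id, z_nm, y_nm, x_nm
#' @param labelmap \code{\link{label_and_classify}} result
#' @param spacing nm per voxel (z, y, x)
#' @return data.frame of class \code{SignedDistanceRecord} rows:
#'   spot_id, nearest_granule_id, signed_distance_nm, excluded,
#'   exclusion_reason. With no granules all records are excluded with
#'   infinite distance.
#' @export
signed_distances <- function(spots, labelmap, spacing) {
  stopifnot(inherits(labelmap, "GranuleLabelMap"), length(spacing) == 3L,
            all(spacing > 0))
  n <- nrow(spots)
  if (length(labelmap$surface_idx) == 0L) {
    return(data.frame(spot_id = spots$spot_id,
                      nearest_granule_id = rep(NA_integer_, n),
                      signed_distance_nm = rep(Inf, n),
                      excluded = rep(TRUE, n),
                      exclusion_reason = rep("no_granules", n)))
  }
  d <- labelmap$shape
  sc <- arrayInd(labelmap$surface_idx, d)
  surf <- cbind((sc[, 1] - 0.5) * spacing[1],
                (sc[, 2] - 0.5) * spacing[2],
                (sc[, 3] - 0.5) * spacing[3])
  owner <- labelmap$surface_label
  pos <- as.matrix(spots[, c("z_nm", "y_nm", "x_nm")])
  best_d2 <- rep(Inf, n)
  best_id <- rep(NA_integer_, n)
  chunk <- max(1L, floor(5e6 / length(owner)))
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(n, s + chunk - 1L)
    d2 <- outer(pos[rows, 1], surf[, 1], "-")^2 +
      outer(pos[rows, 2], surf[, 2], "-")^2 +
      outer(pos[rows, 3], surf[, 3], "-")^2
    for (k in seq_along(rows)) {
      v <- d2[k, ]
      m <- min(v)
      ties <- which(v == m)
      best_d2[rows[k]] <- m
      best_id[rows[k]] <- min(owner[ties])
    }
  }
  vox <- pos_to_voxel(pos, spacing, d)
  lin <- vox[, 1] + (vox[, 2] - 1L) * d[1] + (vox[, 3] - 1L) * d[1] * d[2]
  inside <- labelmap$labels[lin] > 0L
  data.frame(spot_id = spots$spot_id,
             nearest_granule_id = best_id,
             signed_distance_nm = ifelse(inside, -1, 1) * sqrt(best_d2),
             excluded = FALSE,
             exclusion_reason = "none")
}

#' Exclude spots whose nearest granule touches the image border
#'
#' Marks records \code{excluded = TRUE} with reason
#' \code{"border_granule"} when the nearest granule contacts the image
#' boundary, so localization statistics use only granules fully captured
#' in the volume. All records are retained (output length = input
#' length).
#' @param records from \code{\link{signed_distances}}
#' @param labelmap GranuleLabelMap
#' @return records with updated exclusion columns
#' @export
apply_exclusions <- function(records, labelmap) {
  border_ids <- labelmap$granules$granule_id[labelmap$granules$touches_border]
  hit <- !is.na(records$nearest_granule_id) &
    records$nearest_granule_id %in% border_ids &
    !records$excluded
  records$excluded[hit] <- TRUE
  records$exclusion_reason[hit] <- "border_granule"
  records
}

#' Relative-frequency histogram with KDE of signed distances
#'
#' Histogram of non-excluded signed distances in fixed-width bins
#' aligned at zero (default 25 nm), normalized to relative frequencies,
#' with a Gaussian kernel density estimate (Scott's rule bandwidth)
#' evaluated on the histogram support.
#' @param records from \code{\link{signed_distances}}
#' @param bin_width nm
#' @param kde_n evaluation points of the KDE
#' @return list of class \code{DistanceHistogram}: \code{edges},
#'   \code{freq} (sums to 1), \code{kde_x}, \code{kde_y}, \code{n_used},
#'   \code{n_excluded}
#' @export
histogram_with_kde <- function(records, bin_width = 25, kde_n = 512L) {
  x <- records$signed_distance_nm[!records$excluded]
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no non-excluded records to histogram")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(x, breaks = edges, plot = FALSE, right = FALSE)
  kde <- if (length(x) > 1L && stats::sd(x) > 0) {
    stats::density(x, bw = "nrd", n = kde_n, from = lo, to = hi)
  } else {
    list(x = edges, y = rep(NA_real_, length(edges)))
  }
  structure(list(edges = edges, freq = h$counts / length(x),
                 kde_x = kde$x, kde_y = kde$y,
                 n_used = length(x),
                 n_excluded = sum(records$excluded)),
            class = "DistanceHistogram")
}

#' 180-degree in-plane rotation control
#'
#' Maps every spot centroid to its image under a 180-degree rotation
#' about the xy center of the volume (z unchanged): (z, y, x) ->
#' (z, Y - y, X - x) with Y, X the physical y/x extents. Applying the
#' control twice restores the original spots. Randomizes the spatial
#' relation between foci and granules while preserving the foci's own
#' spatial statistics.
#' @param spots data.frame with z_nm, y_nm, x_nm
#' @param image_shape voxel counts (z, y, x)
#' @param spacing nm per voxel (z, y, x)
#' @return spots with rotated coordinates
#' @export
rotation_control <- function(spots, image_shape, spacing) {
  ext <- image_shape * spacing
  out <- spots
  out$y_nm <- ext[2] - spots$y_nm
  out$x_nm <- ext[3] - spots$x_nm
  out
}

#' Uniform random spot control
#'
#' Draws n points uniformly over the half-open physical volume
#' [0, shape * spacing) in z, y and x; the deterministic counterpart of
#' the study's one-million-random-points null.
#' @param n number of points (>= 1)
#' @param image_shape voxel counts (z, y, x)
#' @param spacing nm per voxel (z, y, x)
#' @param seed integer seed
#' @return data.frame: spot_id, z_nm, y_nm, x_nm
#' @export
uniform_random_control <- function(n, image_shape, spacing, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  ext <- image_shape * spacing
  data.frame(spot_id = seq_len(n),
             z_nm = stats::runif(n, 0, ext[1]),
             y_nm = stats::runif(n, 0, ext[2]),
             x_nm = stats::runif(n, 0, ext[3]))
}

#' Write signed-distance records as CSV / histogram as JSON
#' @param records SignedDistanceRecord data.frame
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_distance_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_records
#' @param hist DistanceHistogram
#' @export
write_distance_histogram <- function(hist, path) {
  jsonlite::write_json(unclass(hist), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
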