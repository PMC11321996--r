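#' Binary segmentation of the granule channel
#'
#' Thresholds the granule channel (fixed value or global Otsu) and
#' removes connected components smaller than \code{min_volume} voxels.
#' This deliberately replaces interactive pixel-classifier segmentation
#' with a transparent, reproducible rule; its quality is assessed on
#' phantoms where thresholding is adequate.
#'
#' @param arr 3D array (z, y, x), granule channel
#' @param method \code{"otsu"} or \code{"fixed"}
#' @param threshold required when \code{method = "fixed"}
#' @param min_volume minimum object size in voxels (default 27, a 3x3x3
#'   block)
#' @param connectivity component connectivity for the size filter (26 or 6)
#' @param max_fill granules are sparse objects: while the above-threshold
#'   fraction exceeds this bound, Otsu is re-applied to the
#'   above-threshold values (recursive Otsu, which handles the heavily
#'   skewed histograms of sparse-object volumes)
#' @param min_contrast foreground voxels must exceed the background mean
#'   by this many background standard deviations, otherwise the image is
#'   treated as featureless and an empty mask is returned with a warning
#' @return logical 3D array
#' @export
segment_granules <- function(arr, method = c("otsu", "fixed"),
                             threshold = NULL, min_volume = 27L,
                             connectivity = 26L, max_fill = 0.25,
                             min_contrast = 4) {
  method <- match.arg(method)
  if (method == "fixed") {
    stopifnot(!is.null(threshold))
    t <- threshold
  } else {
    t <- otsu_threshold(arr)
    for (iter in seq_len(5L)) {
      if (mean(arr > t) <= max_fill) break
      t <- otsu_threshold(arr[arr > t])
    }
    fg <- arr > t
    if (!any(fg) ||
        mean(arr[fg]) - mean(arr[!fg]) < min_contrast * stats::sd(arr[!fg])) {
      warning("no voxel population clears the background by ",
              min_contrast, " sd; treating image as featureless ",
              "(empty mask)")
      return(array(FALSE, dim(arr)))
    }
  }
  mask <- arr > t
  if (any(mask) && min_volume > 1L) {
    lab <- label_components(mask, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_volume)
    mask <- array(lab %in% keep, dim(mask))
  }
  if (!any(mask)) warning("segmentation produced an empty mask")
  mask
}

neighbor_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  if (connectivity == 6L) {
    offs <- offs[rowSums(abs(offs)) == 1L, , drop = FALSE]
  } else if (connectivity != 26L) {
    stop("connectivity must be 6 or 26")
  }
  offs
}

#' Label connected components of a 3D binary mask
#'
#' Foreground voxels are vertices; voxels within the chosen neighbourhood
#' (26- or 6-connectivity) are joined by edges and components come from
#' \code{igraph}. Labels are renumbered 1..k in order of each
#' component's smallest linear voxel index, so the labelling is a pure
#' function of the mask.
#' @param mask logical 3D array
#' @param connectivity 26 (default) or 6
#' @return integer array, 0 = background
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  id_of <- array(0L, d)
  id_of[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  offs <- neighbor_offsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[r, ], nrow(coords), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] & nb[, 2] >= 1L & nb[, 2] <= d[2] &
      nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_id <- id_of[nb_lin]
    src <- which(ok)[nb_id > 0L]
    if (length(src)) {
      edges[[length(edges) + 1L]] <- cbind(src, nb_id[nb_id > 0L])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)$membership
  # renumber by first (smallest linear index) voxel of each component
  first_idx <- tapply(fg, comp, min)
  new_id <- integer(max(comp))
  new_id[as.integer(names(sort(first_idx)))] <- seq_along(first_idx)
  lab[fg] <- new_id[comp]
  lab
}

#' Label granules and classify surface vs interior voxels
#'
#' Connected components (default 26-connectivity) of a binary mask are
#' labelled; within each granule a voxel is classified as surface when at
#' least one of its 6 face-adjacent neighbours lies outside the granule
#' or the voxel sits on the image boundary, and interior otherwise.
#' Granules with any voxel on the image border (index 1 or max along any
#' axis) are flagged \code{touches_border} so they can be excluded from
#' distance analyses.
#'
#' @param mask logical 3D array
#' @param connectivity component connectivity (26 or 6)
#' @return list of class \code{GranuleLabelMap}: \code{labels} (integer
#'   array), \code{granules} (data.frame: granule_id, volume_voxels,
#'   n_surface, touches_border, centroid z/y/x in voxels),
#'   \code{surface_idx} (linear indices of surface voxels),
#'   \code{surface_label} (their granule ids), \code{shape}
#' @export
label_and_classify <- function(mask, connectivity = 26L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  d <- dim(mask)
  lab <- label_components(mask, connectivity)
  ng <- max(lab)
  # face-exposed test: a foreground voxel is surface iff some 6-neighbour
  # is background or it lies on the image boundary
  is_surface <- array(FALSE, d)
  if (any(mask)) {
    exposed <- array(FALSE, d)
    for (r in seq_len(nrow(neighbor_offsets(6L)))) {
      off <- neighbor_offsets(6L)[r, ]
      exposed <- exposed | !shift_3d(mask, off[1], off[2], off[3], fill = FALSE)
    }
    border <- array(FALSE, d)
    border[c(1L, d[1]), , ] <- TRUE
    border[, c(1L, d[2]), ] <- TRUE
    border[, , c(1L, d[3])] <- TRUE
    is_surface <- mask & (exposed | border)
  }
  surface_idx <- which(is_surface)
  surface_label <- lab[surface_idx]
  granules <- if (ng == 0L) {
    data.frame(granule_id = integer(), volume_voxels = integer(),
               n_surface = integer(), touches_border = logical(),
               centroid_z = numeric(), centroid_y = numeric(),
               centroid_x = numeric())
  } else {
    fg <- which(lab > 0L)
    ids <- lab[fg]
    coords <- arrayInd(fg, d)
    on_border <- coords[, 1] %in% c(1L, d[1]) |
      coords[, 2] %in% c(1L, d[2]) | coords[, 3] %in% c(1L, d[3])
    data.frame(
      granule_id = seq_len(ng),
      volume_voxels = as.integer(tabulate(ids, ng)),
      n_surface = as.integer(tabulate(surface_label, ng)),
      touches_border = as.logical(tapply(on_border, ids, any)),
      centroid_z = as.numeric(tapply(coords[, 1], ids, mean)),
      centroid_y = as.numeric(tapply(coords[, 2], ids, mean)),
      centroid_x = as.numeric(tapply(coords[, 3], ids, mean)))
  }
  structure(list(labels = lab, granules = granules,
                 surface_idx = surface_idx, surface_label = surface_label,
                 shape = d),
            class = "GranuleLabelMap")
}

#' @export
print.GranuleLabelMap <- function(x, ...) {
  cat(sprintf("GranuleLabelMap: %d granule(s) in %d x %d x %d volume\n",
              nrow(x$granules), x$shape[1], x$shape[2], x$shape[3]))
  if (nrow(x$granules)) {
    cat(sprintf("  border-touching: %d\n", sum(x$granules$touches_border)))
  }
  invisible(x)
}

#' Per-granule summary table
#'
#' Granule id, voxel volume, surface voxel count, border flag and
#' centroid in physical nm.
#' @param labelmap GranuleLabelMap
#' @param spacing nm per voxel (z, y, x)
#' @return data.frame
#' @export
granule_summary <- function(labelmap, spacing) {
  g <- labelmap$granules
  data.frame(granule_id = g$granule_id, volume_voxels = g$volume_voxels,
             n_surface = g$n_surface, touches_border = g$touches_border,
             centroid_z_nm = (g$centroid_z - 0.5) * spacing[1],
             centroid_y_nm = (g$centroid_y - 0.5) * spacing[2],
             centroid_x_nm = (g$centroid_x - 0.5) * spacing[3])
}
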