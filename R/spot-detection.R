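#' Pre-detection threshold scan
#'
#' Band-pass filters a channel with a Laplacian-of-Gaussian matched to
#' the PSF and, for each candidate threshold, counts the local intensity
#' maxima whose filtered value exceeds it. The count is non-increasing
#' in the threshold; plotted on log-log axes it typically shows an
#' exponential rise at low thresholds (noise) and a plateau where every
#' real focus and nothing else is detected.
#'
#' @param arr 3D array (z, y, x), one channel
#' @param threshold_grid ascending thresholds (>= 10 values), or NULL to
#'   build a 40-point geometric grid from the filtered image (from the
#'   90th percentile of positive responses up to the maximum), which
#'   makes the scan equivariant under intensity rescaling
#' @param psf_sigma_vox LoG sigma in voxels (z, y, x)
#' @return list of class \code{ThresholdCurve}: \code{thresholds},
#'   \code{counts}, and the filtered image as attribute
#' @export
predetect <- function(arr, threshold_grid = NULL,
                      psf_sigma_vox = c(2, 2.35, 2.35)) {
  filt <- log_filter(arr, psf_sigma_vox)
  maxima <- which(local_maxima_3d(filt))
  vals <- filt[maxima]
  if (is.null(threshold_grid)) {
    pos <- vals[vals > 0]
    if (length(pos) < 2L) {
      threshold_grid <- seq(1e-6, 1, length.out = 40L)
    } else {
      lo <- stats::quantile(pos, 0.25, names = FALSE)
      hi <- max(pos)
      if (lo <= 0 || hi <= lo) lo <- hi / 1000
      threshold_grid <- exp(seq(log(lo), log(hi), length.out = 40L))
    }
  }
  stopifnot(length(threshold_grid) >= 10L, !is.unsorted(threshold_grid))
  counts <- vapply(threshold_grid, function(t) sum(vals > t), 0L)
  structure(list(thresholds = as.numeric(threshold_grid),
                 counts = counts, candidates = maxima, filtered = filt),
            class = "ThresholdCurve")
}

#' Select a detection threshold at the left edge of the count plateau
#'
#' Scans the log-log slope of the detected-count curve between adjacent
#' grid points and finds the longest contiguous run of grid points where
#' |d log(count) / d log(threshold)| < \code{plateau_tol}; the selected
#' threshold is the smallest threshold of that run (the left side of the
#' plateau, just before counts start rising into the noise). Zero-count
#' thresholds are ignored. Deterministic: ties between equally long runs
#' go to the lower-threshold run.
#'
#' @param curve \code{ThresholdCurve} from \code{\link{predetect}}
#' @param plateau_tol absolute log-log slope below which the curve is
#'   considered flat
#' @param min_run minimum plateau length in grid points
#' @return scalar threshold
#' @export
select_threshold <- function(curve, plateau_tol = 0.2, min_run = 4L) {
  stopifnot(inherits(curve, "ThresholdCurve"))
  keep <- curve$counts > 0
  th <- curve$thresholds[keep]
  ct <- curve$counts[keep]
  if (length(th) < min_run) {
    stop("no plateau: too few thresholds with non-zero counts")
  }
  slope <- abs(diff(log(ct)) / diff(log(th)))
  flat <- slope < plateau_tol
  # runs of consecutive flat intervals; a run of k intervals spans k+1
  # grid points
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & (r$lengths + 1L) >= min_run)
  if (length(runs) == 0L) {
    stop("no plateau of at least ", min_run,
         " points found; supply a manual threshold")
  }
  best <- runs[which.max(r$lengths[runs])]
  th[starts[best]]
}

# least-squares 3D Gaussian fit in a voxel window around a candidate
# maximum; returns NULL when the fit cannot be set up
fit_one_spot <- function(arr, center_idx, window_vox, spacing) {
  d <- dim(arr)
  half <- (window_vox - 1L) %/% 2L
  rng <- lapply(1:3, function(a) {
    max(1L, center_idx[a] - half[a]):min(d[a], center_idx[a] + half[a])
  })
  sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  if (length(sub) < 10L) return(NULL)
  zc <- voxel_centers(d[1], spacing[1])[rng[[1]]]
  yc <- voxel_centers(d[2], spacing[2])[rng[[2]]]
  xc <- voxel_centers(d[3], spacing[3])[rng[[3]]]
  grid <- expand.grid(gz = zc, gy = yc, gx = xc)
  vals <- as.numeric(sub)
  dat <- list(vals = vals, gz = grid$gz, gy = grid$gy, gx = grid$gx)
  bg0 <- min(vals)
  amp0 <- max(vals) - bg0
  if (amp0 <= 0) return(NULL)
  ctr <- c(voxel_centers(d[1], spacing[1])[center_idx[1]],
           voxel_centers(d[2], spacing[2])[center_idx[2]],
           voxel_centers(d[3], spacing[3])[center_idx[3]])
  fit <- NULL
  # exactly symmetric starts can give a singular gradient on clean data;
  # retry from deterministically perturbed starting values
  for (jit in list(c(0, 1), c(0.3, 1.3), c(-0.3, 0.8))) {
    start <- list(A = amp0,
                  mz = ctr[1] + jit[1] * spacing[1],
                  my = ctr[2] + jit[1] * spacing[2],
                  mx = ctr[3] + jit[1] * spacing[3],
                  sz = 2 * jit[2] * spacing[1], sy = 2.5 * jit[2] * spacing[2],
                  sx = 2.5 * jit[2] * spacing[3],
                  B = bg0 - 0.01 * amp0)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        vals ~ A * exp(-((gz - mz)^2 / (2 * sz^2) +
                         (gy - my)^2 / (2 * sy^2) +
                         (gx - mx)^2 / (2 * sx^2))) + B,
        data = dat, start = start,
        lower = c(A = 0, mz = min(zc) - spacing[1], my = min(yc) - spacing[2],
                  mx = min(xc) - spacing[3], sz = spacing[1] / 4,
                  sy = spacing[2] / 4, sx = spacing[3] / 4, B = -Inf),
        upper = c(A = Inf, mz = max(zc) + spacing[1],
                  my = max(yc) + spacing[2],
                  mx = max(xc) + spacing[3], sz = diff(range(zc)) + spacing[1],
                  sy = diff(range(yc)) + spacing[2],
                  sx = diff(range(xc)) + spacing[3], B = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  list(coef = p, converged = fit$convInfo$isConv)
}

#' Detect and fit diffraction-limited foci in one channel
#'
#' Candidates are local maxima of the LoG-filtered channel above
#' \code{threshold}; each candidate is refined by a least-squares 3D
#' Gaussian fit (free amplitude, centroid, per-axis sigma and constant
#' background) in a window around the maximum, yielding sub-voxel
#' centroids in physical nm. Fits that fail to converge, leave the
#' image, or collapse are flagged \code{fit_ok = FALSE} so they can be
#' excluded downstream.
#'
#' @param arr 3D array (z, y, x), one channel
#' @param threshold detection threshold on the LoG response (e.g. from
#'   \code{\link{select_threshold}})
#' @param spacing nm per voxel (z, y, x)
#' @param channel label stored in the output
#' @param window_vox fit window in voxels (z, y, x); odd
#' @param psf_sigma_vox LoG sigma in voxels
#' @return data.frame: spot_id, channel, z_nm, y_nm, x_nm, amplitude,
#'   sigma_z, sigma_y, sigma_x, background, fit_ok
#' @export
fit_spots <- function(arr, threshold, spacing, channel = "ch1",
                      window_vox = c(5L, 7L, 7L),
                      psf_sigma_vox = c(2, 2.35, 2.35)) {
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  filt <- log_filter(arr, psf_sigma_vox)
  cand <- which(local_maxima_3d(filt) & filt > threshold, arr.ind = TRUE)
  d <- dim(arr)
  ext <- d * spacing
  n <- nrow(cand)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    res <- fit_one_spot(arr, cand[i, ], window_vox, spacing)
    if (is.null(res)) {
      ctr <- (cand[i, ] - 0.5) * spacing
      rows[[i]] <- data.frame(z_nm = ctr[1], y_nm = ctr[2], x_nm = ctr[3],
                              amplitude = NA_real_, sigma_z = NA_real_,
                              sigma_y = NA_real_, sigma_x = NA_real_,
                              background = NA_real_, fit_ok = FALSE)
    } else {
      p <- res$coef
      ok <- res$converged &&
        p["mz"] >= 0 && p["mz"] < ext[1] &&
        p["my"] >= 0 && p["my"] < ext[2] &&
        p["mx"] >= 0 && p["mx"] < ext[3] &&
        p["sz"] > 0 && p["sy"] > 0 && p["sx"] > 0 && p["A"] > 0
      rows[[i]] <- data.frame(z_nm = unname(p["mz"]), y_nm = unname(p["my"]),
                              x_nm = unname(p["mx"]),
                              amplitude = unname(p["A"]),
                              sigma_z = unname(p["sz"]),
                              sigma_y = unname(p["sy"]),
                              sigma_x = unname(p["sx"]),
                              background = unname(p["B"]), fit_ok = ok)
    }
  }
  if (n == 0L) {
    return(data.frame(spot_id = integer(), channel = character(),
                      z_nm = numeric(), y_nm = numeric(), x_nm = numeric(),
                      amplitude = numeric(), sigma_z = numeric(),
                      sigma_y = numeric(), sigma_x = numeric(),
                      background = numeric(), fit_ok = logical()))
  }
  out <- do.call(rbind, rows)
  cbind(data.frame(spot_id = seq_len(nrow(out)), channel = channel), out)
}

# mutual nearest-neighbour pairs between two coordinate sets within
# max_disp; ties broken by smaller displacement, then lower index
mutual_nn_pairs <- function(a, b, max_disp) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
  nn_ab <- apply(d2, 1, which.min)
  nn_ba <- apply(d2, 2, which.min)
  i <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab[i]] == i & d2[cbind(i, nn_ab[i])] <= max_disp^2
  out <- data.frame(i = i[mutual], j = nn_ab[i][mutual],
                    d = sqrt(d2[cbind(i[mutual], nn_ab[i][mutual])]))
  out[order(out$d, out$i), , drop = FALSE]
}

#' Link spots across movie frames into tracks
#'
#' Greedy mutual-nearest-neighbour frame-to-frame linking with one-frame
#' gap closing: spots in frame f are first linked to track heads ending
#' at frame f-1 (mutual nearest neighbours within \code{max_disp}), then
#' remaining spots to heads ending at frame f-1-\code{max_gap}. Each
#' spot joins at most one track. Ties are broken by smaller displacement
#' then lower spot index, making the linker deterministic.
#'
#' @param frames list of spot data.frames (as from \code{\link{fit_spots}}),
#'   one per movie frame, each with z_nm, y_nm, x_nm
#' @param max_disp maximum frame-to-frame displacement, nm
#' @param max_gap maximum number of skipped frames closed per link
#' @return list of tracks; each track is a data.frame of linked spots
#'   with a \code{frame} column, carrying attribute \code{gaps} (number
#'   of closed gaps)
#' @export
link_tracks <- function(frames, max_disp = 1000, max_gap = 1L) {
  stopifnot(length(frames) >= 2L)
  coords <- lapply(frames, function(f) {
    as.matrix(f[, c("z_nm", "y_nm", "x_nm"), drop = FALSE])
  })
  # active tracks: list of (spot row indices per frame, last frame)
  tracks <- list()
  assignment <- lapply(frames, function(f) rep(NA_integer_, nrow(f)))
  for (f in seq_along(frames)) {
    linked <- rep(FALSE, nrow(coords[[f]]))
    for (gap in 0:max_gap) {
      prev_f <- f - 1L - gap
      if (prev_f < 1L) break
      head_ids <- which(vapply(tracks, function(tr) tr$last_frame == prev_f,
                               TRUE))
      if (length(head_ids) == 0L) next
      head_pos <- t(vapply(head_ids, function(id) {
        tr <- tracks[[id]]
        coords[[tr$last_frame]][tr$spots[length(tr$spots)], ]
      }, numeric(3)))
      free <- which(!linked)
      if (length(free) == 0L) break
      pairs <- mutual_nn_pairs(head_pos,
                               coords[[f]][free, , drop = FALSE], max_disp)
      for (r in seq_len(nrow(pairs))) {
        id <- head_ids[pairs$i[r]]
        sp <- free[pairs$j[r]]
        tracks[[id]]$spots <- c(tracks[[id]]$spots, sp)
        tracks[[id]]$frames <- c(tracks[[id]]$frames, f)
        tracks[[id]]$gaps <- tracks[[id]]$gaps + gap
        tracks[[id]]$last_frame <- f
        linked[sp] <- TRUE
      }
    }
    for (sp in which(!linked)) {
      tracks[[length(tracks) + 1L]] <-
        list(spots = sp, frames = f, gaps = 0L, last_frame = f)
    }
  }
  lapply(tracks, function(tr) {
    df <- do.call(rbind, Map(function(fr, sp) {
      cbind(frame = fr, frames[[fr]][sp, , drop = FALSE])
    }, tr$frames, tr$spots))
    rownames(df) <- NULL
    attr(df, "gaps") <- tr$gaps
    df
  })
}

#' Keep only long tracks
#'
#' Retains tracks observed in strictly more than \code{min_frames}
#' frames (a 30-frame track is dropped at the default).
#' @param tracks list of tracks from \code{\link{link_tracks}}
#' @param min_frames strict lower bound on observed frames
#' @return filtered list
#' @export
filter_long_tracks <- function(tracks, min_frames = 30L) {
  tracks[vapply(tracks, nrow, 0L) > min_frames]
}
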