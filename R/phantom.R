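#' Placement laws for phantom mRNA foci
#'
#' Constructors describing how mRNA foci are placed relative to the
#' granules of a phantom:
#' \itemize{
#'   \item \code{placement_surface_shell(mean, sd)}: signed distance from
#'     the granule surface drawn from N(mean, sd) nm, direction uniform
#'     on the sphere — emulates border-enriched mRNA.
#'   \item \code{placement_uniform_volume()}: uniform over the physical
#'     volume — the random null.
#'   \item \code{placement_interior_only()}: uniform within a granule.
#'   \item \code{placement_paired_5p3p(offset)}: 3' foci on granule
#'     surfaces with a 5' partner displaced \code{offset} nm radially
#'     outward — emulates the outward orientation of the coding sequence.
#' }
#' @param mean,sd nm, parameters of the surface-shell law
#' @param offset nm, radial 5' displacement
#' @name placement
NULL

#' @rdname placement
#' @export
placement_surface_shell <- function(mean = 0, sd = 50) {
  list(type = "surface_shell", mean = mean, sd = sd)
}

#' @rdname placement
#' @export
placement_uniform_volume <- function() list(type = "uniform_volume")

#' @rdname placement
#' @export
placement_interior_only <- function() list(type = "interior_only")

#' @rdname placement
#' @export
placement_paired_5p3p <- function(offset = 100) {
  list(type = "paired_5p3p", offset = offset)
}

#' Phantom configuration
#'
#' Parameters of a synthetic 3-channel germplasm-like volume: spherical
#' granules, diffraction-limited mRNA foci placed at controlled signed
#' distances from granule surfaces, and nascent-protein foci paired with
#' the translating subset of mRNAs. Defaults mirror a high-resolution
#' confocal acquisition with 42.5 nm lateral and 150 nm axial sampling.
#'
#' @param shape_zyx voxel counts (z, y, x)
#' @param spacing_zyx nm per voxel (z, y, x)
#' @param n_granules number of granules
#' @param granule_radius_range nm, min and max sphere radius; radii must
#'   exceed the largest voxel spacing so granules span >= 2 voxels
#' @param granule_intensity photon counts at granule interior
#' @param n_rna_spots number of mRNA foci
#' @param translating_fraction proportion of mRNA foci given a protein
#'   partner, in [0, 1]
#' @param placement_law one of the \code{\link{placement}} constructors
#' @param pairing_dist_nm max RNA-protein offset for translating pairs
#' @param coloc_dist_nm the co-localization calling radius downstream
#' @param nontranslating_clearance_nm minimum distance kept between any
#'   protein focus and every non-translating mRNA focus. At the default
#'   (equal to \code{coloc_dist_nm}) ground-truth translating labels are
#'   unambiguous under the calling rule; lowering it permits denser
#'   mixed-label geometries (e.g. surface vs interior populations of the
#'   same granule) at the cost of rare chance co-localizations.
#' @param psf_sigma_zyx nm, Gaussian PSF sigma per axis
#' @param photon_scale peak photon count of a rendered focus
#' @param gaussian_noise_sd additive read-noise sd (photons)
#' @param poisson_noise apply Poisson shot noise to the rendered photon
#'   counts (disable together with \code{gaussian_noise_sd = 0} for
#'   noise-free renderings)
#' @param seed integer seed; all phantom randomness flows from it
#' @return a \code{PhantomConfig} list
#' @export
phantom_config <- function(shape_zyx = c(16L, 128L, 128L),
                           spacing_zyx = c(150, 42.5, 42.5),
                           n_granules = 15L,
                           granule_radius_range = c(200, 350),
                           granule_intensity = 40,
                           n_rna_spots = 80L,
                           translating_fraction = 0.4,
                           placement_law = placement_surface_shell(),
                           pairing_dist_nm = 150,
                           coloc_dist_nm = 400,
                           nontranslating_clearance_nm = coloc_dist_nm,
                           psf_sigma_zyx = c(300, 100, 100),
                           photon_scale = 200,
                           gaussian_noise_sd = 2,
                           poisson_noise = TRUE,
                           seed = 1L) {
  cfg <- list(shape_zyx = as.integer(shape_zyx),
              spacing_zyx = as.numeric(spacing_zyx),
              n_granules = as.integer(n_granules),
              granule_radius_range = as.numeric(granule_radius_range),
              granule_intensity = granule_intensity,
              n_rna_spots = as.integer(n_rna_spots),
              translating_fraction = translating_fraction,
              placement_law = placement_law,
              pairing_dist_nm = pairing_dist_nm,
              coloc_dist_nm = coloc_dist_nm,
              nontranslating_clearance_nm = nontranslating_clearance_nm,
              psf_sigma_zyx = as.numeric(psf_sigma_zyx),
              photon_scale = photon_scale,
              gaussian_noise_sd = gaussian_noise_sd,
              poisson_noise = isTRUE(poisson_noise),
              seed = as.integer(seed))
  stopifnot(length(cfg$shape_zyx) == 3L, all(cfg$shape_zyx >= 1L),
            length(cfg$spacing_zyx) == 3L, all(cfg$spacing_zyx > 0),
            cfg$n_granules >= 0L, cfg$n_rna_spots >= 0L,
            cfg$translating_fraction >= 0, cfg$translating_fraction <= 1,
            cfg$pairing_dist_nm > 0, cfg$coloc_dist_nm >= cfg$pairing_dist_nm,
            cfg$nontranslating_clearance_nm >= 0,
            all(cfg$psf_sigma_zyx >= 0))
  if (cfg$n_granules > 0L &&
      cfg$granule_radius_range[1] <= max(cfg$spacing_zyx)) {
    stop("granule radii must exceed the largest voxel spacing (",
         max(cfg$spacing_zyx), " nm)")
  }
  class(cfg) <- "PhantomConfig"
  cfg
}

# uniform direction on the unit sphere, n x 3 (z, y, x)
runif_sphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Analytic signed distance from points to the nearest sphere surface
#'
#' For spherical granules the signed distance of a point to the nearest
#' granule surface is min over granules of |x - c| - r: negative inside a
#' granule, positive outside. This is the exact ground-truth counterpart
#' of the voxel-based \code{\link{signed_distances}}.
#' @param pos n x 3 matrix of nm positions (z, y, x)
#' @param granules data.frame with z_nm, y_nm, x_nm, radius_nm
#' @return list(distance = nm vector, granule_id = nearest granule index;
#'   Inf / NA when there are no granules)
#' @export
sphere_signed_distance <- function(pos, granules) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  n <- nrow(pos)
  if (is.null(granules) || nrow(granules) == 0L) {
    return(list(distance = rep(Inf, n), granule_id = rep(NA_integer_, n)))
  }
  best <- rep(Inf, n); id <- rep(NA_integer_, n)
  for (g in seq_len(nrow(granules))) {
    d <- sqrt((pos[, 1] - granules$z_nm[g])^2 +
              (pos[, 2] - granules$y_nm[g])^2 +
              (pos[, 3] - granules$x_nm[g])^2) - granules$radius_nm[g]
    upd <- d < best
    best[upd] <- d[upd]; id[upd] <- g
  }
  list(distance = best, granule_id = id)
}

place_granules <- function(cfg) {
  ext <- cfg$shape_zyx * cfg$spacing_zyx
  n <- cfg$n_granules
  if (n == 0L) {
    return(data.frame(granule_id = integer(), z_nm = numeric(),
                      y_nm = numeric(), x_nm = numeric(),
                      radius_nm = numeric()))
  }
  centers <- matrix(NA_real_, n, 3)
  radii <- stats::runif(n, cfg$granule_radius_range[1],
                        cfg$granule_radius_range[2])
  max_try <- 1000L
  for (g in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_try)) {
      p <- vapply(1:3, function(a)
        stats::runif(1, radii[g], ext[a] - radii[g]), 0)
      if (any(p < radii[g])) next
      if (g > 1L) {
        prev <- centers[seq_len(g - 1L), , drop = FALSE]
        sep <- sqrt(rowSums(sweep(prev, 2, p)^2))
        if (any(sep < radii[g] + radii[seq_len(g - 1L)] + 50)) next
      }
      centers[g, ] <- p
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place ", n, " non-overlapping granules; ",
           "configuration too crowded")
    }
  }
  data.frame(granule_id = seq_len(n), z_nm = centers[, 1],
             y_nm = centers[, 2], x_nm = centers[, 3], radius_nm = radii)
}

# draw one candidate RNA position (plus radial direction for paired law)
draw_rna_candidate <- function(law, granules, ext) {
  switch(law$type,
    uniform_volume = list(pos = c(stats::runif(1, 0, ext[1]),
                                  stats::runif(1, 0, ext[2]),
                                  stats::runif(1, 0, ext[3])),
                          dir = NULL),
    surface_shell = {
      g <- sample.int(nrow(granules), 1L)
      u <- runif_sphere(1)[1, ]
      s <- stats::rnorm(1, law$mean, law$sd)
      list(pos = as.numeric(granules[g, c("z_nm", "y_nm", "x_nm")]) +
             u * (granules$radius_nm[g] + s), dir = u)
    },
    interior_only = {
      g <- sample.int(nrow(granules), 1L)
      u <- runif_sphere(1)[1, ]
      r <- granules$radius_nm[g] * stats::runif(1)^(1 / 3)
      list(pos = as.numeric(granules[g, c("z_nm", "y_nm", "x_nm")]) + u * r,
           dir = u)
    },
    paired_5p3p = {
      g <- sample.int(nrow(granules), 1L)
      u <- runif_sphere(1)[1, ]
      list(pos = as.numeric(granules[g, c("z_nm", "y_nm", "x_nm")]) +
             u * granules$radius_nm[g], dir = u)
    },
    stop("unknown placement law: ", law$type))
}

# Sequential RNA placement with rejection. Opposite-label spots (one
# translating, one not) are kept at least `min_sep` apart so a protein
# partner clear of all non-translating RNAs exists; same-label spots are
# unconstrained.
place_rna <- function(cfg, granules, translating) {
  ext <- cfg$shape_zyx * cfg$spacing_zyx
  n <- cfg$n_rna_spots
  law <- cfg$placement_law
  if (n == 0L) {
    out <- matrix(numeric(), 0, 3)
    attr(out, "dir") <- matrix(numeric(), 0, 3)
    return(out)
  }
  if (law$type != "uniform_volume" && nrow(granules) == 0L) {
    stop("placement law '", law$type, "' requires at least one granule")
  }
  min_sep <- cfg$nontranslating_clearance_nm
  constrain <- any(translating) && !all(translating) && min_sep > 0
  out <- matrix(NA_real_, n, 3)
  dirs <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(2000L)) {
      cand <- draw_rna_candidate(law, granules, ext)
      p <- cand$pos
      if (any(p < 0) || any(p >= ext)) next
      if (constrain && i > 1L) {
        prev <- seq_len(i - 1L)
        opp <- prev[translating[prev] != translating[i]]
        if (length(opp)) {
          d2 <- (out[opp, 1] - p[1])^2 + (out[opp, 2] - p[2])^2 +
            (out[opp, 3] - p[3])^2
          if (any(d2 < min_sep^2)) next
        }
      }
      out[i, ] <- p
      if (!is.null(cand$dir)) dirs[i, ] <- cand$dir
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place RNA focus ", i, " under the clearance ",
           "constraint; configuration too crowded")
    }
  }
  attr(out, "dir") <- dirs
  out
}

# protein partner positions for translating RNAs; each partner is kept
# at least nontranslating_clearance_nm away from every non-translating
# RNA (at the default clearance = coloc radius, ground-truth labels are
# unambiguous under the calling rule)
place_protein <- function(cfg, rna_pos, translating) {
  ext <- cfg$shape_zyx * cfg$spacing_zyx
  idx <- which(translating)
  nt_pos <- rna_pos[!translating, , drop = FALSE]
  clear <- cfg$nontranslating_clearance_nm
  out <- matrix(NA_real_, length(idx), 3)
  for (j in seq_along(idx)) {
    base <- rna_pos[idx[j], ]
    placed <- FALSE
    for (k in seq_len(1000L)) {
      u <- runif_sphere(1)
      p <- base + u[1, ] * stats::runif(1, 0, cfg$pairing_dist_nm)
      if (any(p < 0) || any(p >= ext)) next
      if (nrow(nt_pos) > 0L && clear > 0) {
        d2 <- rowSums(sweep(nt_pos, 2, p)^2)
        if (any(d2 <= clear^2)) next
      }
      out[j, ] <- p
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place a protein focus clear of non-translating RNAs; ",
           "phantom too crowded")
    }
  }
  out
}

# add a PSF-shaped point source at a physical position (separable outer
# product on a +/- 4 sigma window)
add_spot <- function(arr, pos_nm, amp, sigma_nm, spacing) {
  d <- dim(arr)
  win <- lapply(1:3, function(a) {
    c_idx <- pos_nm[a] / spacing[a] + 0.5  # fractional voxel index
    r <- max(1, ceiling(4 * sigma_nm[a] / spacing[a]))
    idx <- max(1L, floor(c_idx - r)):min(d[a], ceiling(c_idx + r))
    prof <- exp(-(voxel_centers(d[a], spacing[a])[idx] - pos_nm[a])^2 /
                  (2 * sigma_nm[a]^2))
    list(idx = idx, prof = prof)
  })
  patch <- amp * (win[[1]]$prof %o% win[[2]]$prof %o% win[[3]]$prof)
  arr[win[[1]]$idx, win[[2]]$idx, win[[3]]$idx] <-
    arr[win[[1]]$idx, win[[2]]$idx, win[[3]]$idx] + patch
  arr
}

render_spots_channel <- function(cfg, pos) {
  arr <- array(0, cfg$shape_zyx)
  if (nrow(pos) == 0L) return(arr)
  for (i in seq_len(nrow(pos))) {
    arr <- add_spot(arr, pos[i, ], cfg$photon_scale,
                    cfg$psf_sigma_zyx, cfg$spacing_zyx)
  }
  arr
}

render_granule_channel <- function(cfg, granules) {
  arr <- array(0, cfg$shape_zyx)
  if (nrow(granules) == 0L) return(arr)
  zc <- voxel_centers(cfg$shape_zyx[1], cfg$spacing_zyx[1])
  yc <- voxel_centers(cfg$shape_zyx[2], cfg$spacing_zyx[2])
  xc <- voxel_centers(cfg$shape_zyx[3], cfg$spacing_zyx[3])
  for (g in seq_len(nrow(granules))) {
    dz2 <- (zc - granules$z_nm[g])^2
    dy2 <- (yc - granules$y_nm[g])^2
    dx2 <- (xc - granules$x_nm[g])^2
    inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= granules$radius_nm[g]^2
    arr[inside] <- cfg$granule_intensity
  }
  gauss_blur_3d(arr, cfg$psf_sigma_zyx / cfg$spacing_zyx)
}

apply_camera_noise <- function(arr, read_sd, poisson = TRUE) {
  n <- length(arr)
  base <- if (poisson) {
    stats::rpois(n, lambda = pmax(as.numeric(arr), 0))
  } else {
    as.numeric(arr)
  }
  if (read_sd > 0) base <- base + stats::rnorm(n, 0, read_sd)
  array(base, dim(arr))
}

#' Generate a 3-channel phantom volume with ground truth
#'
#' Renders spherical granules (granule channel), mRNA foci (rna channel)
#' and nascent-protein foci paired with the translating mRNAs (protein
#' channel) into a Poisson + Gaussian noise model, and returns the exact
#' geometry used so downstream stages can be scored against known truth.
#' With \code{render = FALSE} only the geometry is generated, which is
#' cheap and sufficient for tests that operate on coordinates.
#'
#' @param config a \code{\link{phantom_config}}
#' @param render render voxel data (TRUE) or return geometry only
#' @return list with elements \code{stack} (ImageStack or NULL) and
#'   \code{truth} (class \code{GroundTruth}: granules, rna, protein
#'   data.frames and the config)
#' @export
generate_phantom <- function(config, render = TRUE) {
  stopifnot(inherits(config, "PhantomConfig"))
  set.seed(config$seed)
  granules <- place_granules(config)
  n <- config$n_rna_spots
  paired <- !is.null(config$placement_law$type) &&
    config$placement_law$type == "paired_5p3p"
  if (paired) {
    translating <- rep(TRUE, n)
  } else {
    n_tr <- round(config$translating_fraction * n)
    translating <- rep(FALSE, n)
    if (n_tr > 0L) translating[sample.int(n, n_tr)] <- TRUE
  }
  rna_pos <- place_rna(config, granules, translating)
  if (paired) {
    dirs <- attr(rna_pos, "dir")
    prot_pos <- rna_pos + dirs * config$placement_law$offset
    prot_rna <- seq_len(n)
  } else {
    prot_pos <- place_protein(config, rna_pos, translating)
    prot_rna <- which(translating)
  }
  sd_true <- sphere_signed_distance(rna_pos, granules)
  rna <- data.frame(spot_id = seq_len(n),
                    z_nm = rna_pos[, 1], y_nm = rna_pos[, 2],
                    x_nm = rna_pos[, 3],
                    translating = translating,
                    true_signed_distance_nm = sd_true$distance,
                    true_granule_id = sd_true$granule_id)
  protein <- data.frame(spot_id = seq_len(nrow(prot_pos)),
                        rna_spot_id = prot_rna,
                        z_nm = prot_pos[, 1], y_nm = prot_pos[, 2],
                        x_nm = prot_pos[, 3])
  truth <- structure(list(granules = granules, rna = rna,
                          protein = protein, config = config),
                     class = "GroundTruth")
  stack <- NULL
  if (render) {
    gran_ch <- render_granule_channel(config, granules)
    rna_ch <- render_spots_channel(config, rna_pos)
    prot_ch <- render_spots_channel(config, prot_pos)
    arr <- array(0, c(config$shape_zyx, 3L))
    arr[, , , 1] <- apply_camera_noise(gran_ch, config$gaussian_noise_sd,
                                       config$poisson_noise)
    arr[, , , 2] <- apply_camera_noise(rna_ch, config$gaussian_noise_sd,
                                       config$poisson_noise)
    arr[, , , 3] <- apply_camera_noise(prot_ch, config$gaussian_noise_sd,
                                       config$poisson_noise)
    stack <- image_stack(arr, config$spacing_zyx,
                         c("granule", "rna", "protein"))
  }
  list(stack = stack, truth = truth)
}

#' Write phantom ground truth as CSV tables
#'
#' Writes \code{granules.csv}, \code{rna.csv} and \code{protein.csv}
#' (one row per object, physical nm coordinates) into \code{dir}.
#' @param truth GroundTruth
#' @param dir output directory (created if missing)
#' @return \code{dir}, invisibly
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "GroundTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$granules, file.path(dir, "granules.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$rna, file.path(dir, "rna.csv"), row.names = FALSE)
  utils::write.csv(truth$protein, file.path(dir, "protein.csv"),
                   row.names = FALSE)
  invisible(dir)
}
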