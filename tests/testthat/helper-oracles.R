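# Independent brute-force oracles used to validate the fast
# implementations. These deliberately share no code with the package
# internals: plain loops and first-principles definitions.

# flood-fill connected-component labeling (queue-based, per definition)
oracle_label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (lin in which(mask)) {
    if (lab[lin] > 0L) next
    nxt <- nxt + 1L
    queue <- lin
    lab[lin] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- cc + offs[r, ]
        if (any(nb < 1L) || any(nb > d)) next
        nl <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[nl] && lab[nl] == 0L) {
          lab[nl] <- nxt
          queue <- c(queue, nl)
        }
      }
    }
  }
  lab
}

# per-definition surface test: scan the 6 face neighbours of every
# foreground voxel
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (lin in which(mask)) {
    cc <- arrayInd(lin, d)
    surf <- FALSE
    for (r in 1:6) {
      nb <- cc + offs[r, ]
      if (any(nb < 1L) || any(nb > d)) { surf <- TRUE; break }
      if (!mask[nb[1], nb[2], nb[3]]) { surf <- TRUE; break }
    }
    out[lin] <- surf
  }
  out
}

# exhaustive signed distance: min over every surface-voxel center, ties
# to the lower granule id, sign from the containing voxel's label
oracle_signed_distance <- function(spot_nm, labelmap, spacing) {
  d <- labelmap$shape
  sidx <- labelmap$surface_idx
  sc <- arrayInd(sidx, d)
  best <- Inf
  best_id <- NA_integer_
  for (k in seq_along(sidx)) {
    dd <- sqrt(((sc[k, 1] - 0.5) * spacing[1] - spot_nm[1])^2 +
               ((sc[k, 2] - 0.5) * spacing[2] - spot_nm[2])^2 +
               ((sc[k, 3] - 0.5) * spacing[3] - spot_nm[3])^2)
    id <- labelmap$surface_label[k]
    if (dd < best || (dd == best && id < best_id)) {
      best <- dd
      best_id <- id
    }
  }
  vox <- pmin(pmax(floor(spot_nm / spacing) + 1, 1), d)
  inside <- labelmap$labels[vox[1], vox[2], vox[3]] > 0L
  list(distance = if (inside) -best else best, granule_id = best_id)
}

# random blob-ish binary mask: union of a few random boxes/balls
random_mask <- function(shape, n_obj = 3L) {
  mask <- array(FALSE, shape)
  for (i in seq_len(n_obj)) {
    c0 <- sapply(shape, function(n) sample.int(n, 1))
    r <- sample(1:3, 3, replace = TRUE)
    zr <- max(1, c0[1] - r[1]):min(shape[1], c0[1] + r[1])
    yr <- max(1, c0[2] - r[2]):min(shape[2], c0[2] + r[2])
    xr <- max(1, c0[3] - r[3]):min(shape[3], c0[3] + r[3])
    mask[zr, yr, xr] <- TRUE
  }
  mask
}

# voxelized solid sphere mask on the package's voxel-center grid
sphere_mask <- function(shape, spacing, center_nm, radius_nm) {
  zc <- (seq_len(shape[1]) - 0.5) * spacing[1]
  yc <- (seq_len(shape[2]) - 0.5) * spacing[2]
  xc <- (seq_len(shape[3]) - 0.5) * spacing[3]
  outer(outer((zc - center_nm[1])^2, (yc - center_nm[2])^2, "+"),
        (xc - center_nm[3])^2, "+") <= radius_nm^2
}

# quadrature CDF of the analytic signed distance of a uniform point in
# the box to a set of sphere surfaces (midpoint rule on a fine grid)
oracle_distance_cdf <- function(granules, ext, eval_at, cell_nm = 25) {
  ns <- pmax(2L, round(ext / cell_nm))
  zc <- (seq_len(ns[1]) - 0.5) * ext[1] / ns[1]
  yc <- (seq_len(ns[2]) - 0.5) * ext[2] / ns[2]
  xc <- (seq_len(ns[3]) - 0.5) * ext[3] / ns[3]
  best <- array(Inf, ns)
  for (g in seq_len(nrow(granules))) {
    dd <- sqrt(outer(outer((zc - granules$z_nm[g])^2,
                           (yc - granules$y_nm[g])^2, "+"),
                     (xc - granules$x_nm[g])^2, "+")) - granules$radius_nm[g]
    best <- pmin(best, dd)
  }
  v <- as.numeric(best)
  vapply(eval_at, function(s) mean(v <= s), 0)
}

# small well-separated spot field: positions on a jittered grid with a
# guaranteed minimum pairwise distance
separated_positions <- function(n, ext, min_sep) {
  pos <- matrix(NA_real_, 0, 3)
  for (it in seq_len(20000L)) {
    if (nrow(pos) >= n) break
    p <- c(runif(1, 0.18, 0.82) * ext[1], runif(1, 0.05, 0.95) * ext[2],
           runif(1, 0.05, 0.95) * ext[3])
    if (nrow(pos) == 0 || min(sqrt(rowSums(sweep(pos, 2, p)^2))) > min_sep) {
      pos <- rbind(pos, p)
    }
  }
  if (nrow(pos) < n) stop("could not pack ", n, " separated positions")
  pos
}
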