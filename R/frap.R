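#' FRAP curve container
#'
#' @param t frame times in seconds, strictly increasing
#' @param intensity fluorescence per frame (a.u.)
#' @param bleach_index index of the first post-bleach frame
#' @param prebleach_frames number of frames acquired before the bleach
#' @param sem optional per-frame standard error (stochastic ensembles)
#' @return object of class \code{FrapCurve}
#' @export
frap_curve <- function(t, intensity, bleach_index, prebleach_frames,
                       sem = NULL) {
  stopifnot(length(t) == length(intensity), all(diff(t) > 0),
            prebleach_frames >= 1L, bleach_index >= prebleach_frames)
  structure(list(t = as.numeric(t), intensity = as.numeric(intensity),
                 bleach_index = as.integer(bleach_index),
                 prebleach_frames = as.integer(prebleach_frames),
                 sem = sem),
            class = "FrapCurve")
}

#' FRAP simulation configuration
#'
#' Parameters of the polysome photobleaching model. A polysome carries an
#' N-terminal epitope array of \code{L1} codons followed by a downstream
#' coding sequence of \code{L2} codons; ribosomes initiate at constant
#' rate, elongate at \code{v} codons/s, and release immediately on
#' completion, so the steady-state prebleach intensity is proportional to
#' the effective ORF length 0.5*L1 + L2. Neither \code{L1} nor \code{L2}
#' has a canonical value; the defaults are round numbers for simulation
#' studies and should be set to the construct at hand.
#'
#' @param I0 prebleach intensity (a.u.)
#' @param v elongation rate, codons per second (> 0; 0 allowed in the
#'   stochastic simulator to model frozen ribosomes)
#' @param L1 epitope-array length, codons
#' @param L2 downstream CDS length, codons
#' @param bleach_time seconds from acquisition start to the bleach
#' @param frame_interval seconds per frame
#' @param n_frames total frames
#' @param residual_fraction fraction of I0 remaining right after bleach
#' @param noise_sd_fraction multiplicative noise sd (fraction of signal)
#' @param ribosome_density ribosomes per codon (stochastic simulator)
#' @param seed integer seed
#' @return object of class \code{FrapSimConfig}
#' @export
frap_sim_config <- function(I0 = 1, v = 4, L1 = 200, L2 = 400,
                            bleach_time = 30, frame_interval = 10,
                            n_frames = 40, residual_fraction = 0,
                            noise_sd_fraction = 0,
                            ribosome_density = 0.01, seed = 1L) {
  cfg <- list(I0 = I0, v = v, L1 = L1, L2 = L2, bleach_time = bleach_time,
              frame_interval = frame_interval, n_frames = as.integer(n_frames),
              residual_fraction = residual_fraction,
              noise_sd_fraction = noise_sd_fraction,
              ribosome_density = ribosome_density, seed = as.integer(seed))
  stopifnot(cfg$I0 > 0, cfg$v >= 0, cfg$L1 > 0, cfg$L2 > 0,
            cfg$residual_fraction >= 0, cfg$residual_fraction < 1,
            cfg$noise_sd_fraction >= 0, cfg$ribosome_density > 0,
            cfg$bleach_time > 0)
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if ((cfg$n_frames - 1L) * cfg$frame_interval <= cfg$bleach_time) {
    stop("n_frames too few to span the bleach event")
  }
  class(cfg) <- "FrapSimConfig"
  cfg
}

#' Analytic three-phase FRAP recovery (complete bleach)
#'
#' Recovery of a polysome's unbleached-epitope fluorescence at time
#' \code{tau} seconds after a complete bleach, under uniform ribosome
#' density, constant initiation and elongation, stable epitope labelling
#' and immediate release:
#' \itemize{
#'   \item linear phase, tau <= L2/v:
#'     I = 2 v tau I0 / (L1 + 2 L2);
#'   \item slow-down phase, L2/v < tau <= (L1+L2)/v:
#'     I = I0 - I0 (L1 + L2 - v tau)^2 / (L1 (L1 + 2 L2));
#'   \item plateau at I0 for tau > (L1+L2)/v.
#' }
#' The linear phase ends when intensity reaches I0 * L2 / (0.5 L1 + L2).
#' @param tau seconds after bleach (vectorized; negative values return I0)
#' @param I0,v,L1,L2 model parameters (see \code{\link{frap_sim_config}})
#' @return intensity vector
#' @export
frap_recovery_analytic <- function(tau, I0, v, L1, L2) {
  out <- numeric(length(tau))
  pre <- tau < 0
  out[pre] <- I0
  if (v == 0) {
    out[!pre] <- 0
    return(out)
  }
  t1 <- L2 / v
  t2 <- (L1 + L2) / v
  lin <- !pre & tau <= t1
  mid <- !pre & tau > t1 & tau <= t2
  out[lin] <- 2 * v * tau[lin] * I0 / (L1 + 2 * L2)
  out[mid] <- I0 - I0 * (L1 + L2 - v * tau[mid])^2 / (L1 * (L1 + 2 * L2))
  out[!pre & tau > t2] <- I0
  out
}

#' Simulate a FRAP time series from the analytic recovery model
#'
#' Frames before \code{bleach_time} sit at I0; from the bleach on, the
#' displayed intensity is \code{residual_fraction * I0 + recovery}
#' (capped at I0), i.e. incomplete bleaching is modelled as an additive
#' offset that leaves the linear-phase slope untouched; recovery follows
#' \code{\link{frap_recovery_analytic}}. Multiplicative Gaussian noise is
#' applied per frame when \code{noise_sd_fraction > 0}.
#' @param config \code{\link{frap_sim_config}}
#' @return \code{\link{frap_curve}}
#' @export
simulate_frap_curve <- function(config) {
  stopifnot(inherits(config, "FrapSimConfig"))
  set.seed(config$seed)
  t <- (seq_len(config$n_frames) - 1L) * config$frame_interval
  pre <- t < config$bleach_time
  tau <- t - config$bleach_time
  r <- config$residual_fraction
  I <- ifelse(pre, config$I0,
              pmin(config$I0,
                   r * config$I0 +
                     frap_recovery_analytic(tau, config$I0, config$v,
                                            config$L1, config$L2)))
  if (config$noise_sd_fraction > 0) {
    I <- I * (1 + stats::rnorm(length(I), 0, config$noise_sd_fraction))
  }
  frap_curve(t, I, bleach_index = which(!pre)[1],
             prebleach_frames = sum(pre))
}

#' Event-driven stochastic FRAP simulator (independent oracle)
#'
#' Simulates explicit ribosomes on \code{n_mrnas} independent mRNAs:
#' steady-state initial occupancy Poisson(density * (L1+L2)) with uniform
#' positions, new initiations as a Poisson process of rate density * v,
#' elongation at v codons/s, immediate release at L1+L2. Epitopes
#' synthesized before the bleach are dark afterwards; a ribosome's
#' unbleached signal is the number of codons it traversed within the
#' epitope array [0, L1] since the bleach. The ensemble mean converges to
#' \code{\link{frap_recovery_analytic}} as n_mrnas grows.
#' @param config \code{\link{frap_sim_config}}
#' @param n_mrnas ensemble size (>= 1)
#' @param chunk internal vectorization block size
#' @return \code{\link{frap_curve}} with per-frame \code{sem}
#' @export
simulate_ribosomes_stochastic <- function(config, n_mrnas, chunk = 500L) {
  stopifnot(inherits(config, "FrapSimConfig"), n_mrnas >= 1)
  set.seed(config$seed)
  L <- config$L1 + config$L2
  t <- (seq_len(config$n_frames) - 1L) * config$frame_interval
  tb <- config$bleach_time
  pre <- t < tb
  d <- config$ribosome_density
  v <- config$v
  T_end <- max(t)
  traces <- matrix(0, n_mrnas, length(t))
  done <- 0L
  while (done < n_mrnas) {
    m <- min(chunk, n_mrnas - done)
    # one big ribosome table for this block: mRNA id + initiation time.
    # initial ribosomes at position p0 are equivalent to initiation at
    # time -p0/v (v > 0); for v = 0 positions are frozen at p0.
    n_init <- stats::rpois(m, d * L)
    mrna_a <- rep.int(seq_len(m), n_init)
    p0 <- stats::runif(length(mrna_a), 0, L)
    if (v > 0) {
      n_new <- stats::rpois(m, d * v * T_end)
      mrna_b <- rep.int(seq_len(m), n_new)
      t0 <- c(-p0 / v, stats::runif(length(mrna_b), 0, T_end))
      mrna <- c(mrna_a, mrna_b)
    } else {
      t0 <- rep(NA_real_, length(mrna_a))  # unused; frozen positions
      mrna <- mrna_a
    }
    for (f in seq_along(t)) {
      if (v > 0) {
        p <- v * (t[f] - t0)
        pb <- v * (tb - t0)
      } else {
        p <- p0
        pb <- p0
      }
      present <- p >= 0 & p <= L
      if (pre[f]) {
        contrib <- pmin(pmax(p, 0), config$L1) / config$L1
      } else {
        contrib <- (pmin(pmax(p, 0), config$L1) -
                      pmin(pmax(pb, 0), config$L1)) / config$L1
      }
      contrib[!present] <- 0
      s <- rowsum(contrib, mrna)
      traces[done + as.integer(rownames(s)), f] <- s
    }
    done <- done + m
  }
  # scale epitope counts to the configured prebleach intensity and add
  # the residual (unbleached) offset after the bleach
  scale <- config$I0 / (d * (0.5 * config$L1 + config$L2))
  r <- config$residual_fraction
  traces <- traces * scale
  traces[, !pre] <- r * config$I0 + traces[, !pre]
  m_tr <- colMeans(traces)
  sem <- apply(traces, 2, stats::sd) / sqrt(n_mrnas)
  frap_curve(t, m_tr, bleach_index = which(!pre)[1],
             prebleach_frames = sum(pre), sem = sem)
}

#' Estimate the translation elongation rate from a FRAP curve
#'
#' Fits the linear recovery phase. The prebleach intensity I0 is the mean
#' of the prebleach frames; the linear phase runs from the first
#' post-bleach frame until the intensity first exceeds the analytic
#' boundary I0 * L2 / (0.5 L1 + L2); the slope comes from an ordinary
#' least-squares line with free intercept (the intercept absorbs residual
#' post-bleach signal), and the elongation rate is
#' v = slope * (L1 + 2 L2) / (2 I0).
#' @param curve \code{\link{frap_curve}}
#' @param L1,L2 construct lengths in codons
#' @param min_points minimum frames required in the linear window
#' @return list of class \code{ElongationFit}: \code{v_hat} (codons/s),
#'   \code{slope}, \code{I0_hat}, \code{plateau_entry_intensity},
#'   \code{linear_window} (frame indices), \code{r_squared},
#'   \code{converged}
#' @export
fit_elongation_rate <- function(curve, L1, L2, min_points = 3L) {
  stopifnot(inherits(curve, "FrapCurve"), L1 > 0, L2 > 0)
  pre_idx <- seq_len(curve$prebleach_frames)
  I0_hat <- mean(curve$intensity[pre_idx])
  boundary <- I0_hat * L2 / (0.5 * L1 + L2)
  post <- seq(curve$bleach_index, length(curve$t))
  crossed <- post[curve$intensity[post] >= boundary]
  converged <- TRUE
  if (length(crossed) == 0L) {
    window <- post
    converged <- FALSE  # never reaches the phase boundary
  } else {
    window <- post[post < crossed[1]]
  }
  if (length(window) < min_points) {
    # too few frames below the boundary: extend to the minimum count
    window <- post[seq_len(min(length(post), max(min_points, length(window))))]
    converged <- FALSE
  }
  tt <- curve$t[window] - curve$t[curve$bleach_index]
  yy <- curve$intensity[window]
  fit <- stats::lm(yy ~ tt)
  slope <- unname(stats::coef(fit)[2])
  # suppress the "essentially perfect fit" note on noise-free curves
  r2 <- suppressWarnings(summary(fit)$r.squared)
  v_hat <- slope * (L1 + 2 * L2) / (2 * I0_hat)
  if (!is.finite(slope) || slope <= 0) converged <- FALSE
  structure(list(v_hat = v_hat, slope = slope, I0_hat = I0_hat,
                 plateau_entry_intensity = boundary,
                 linear_window = window, r_squared = r2,
                 converged = converged, L1 = L1, L2 = L2),
            class = "ElongationFit")
}

#' Ribosome occupancy from polysome and single-peptide intensities
#'
#' Given the mean polysome intensity F and the single mature-peptide
#' intensity F0, the ribosome density per codon is
#' d = F / (F0 * (L2 + 0.5 L1)) (the effective fluorescent ORF length is
#' 0.5 L1 + L2 because ribosomes inside the epitope array carry on
#' average half of it). Also reported: ribosomes per mRNA d * (L1 + L2)
#' and nucleotides per ribosome 3 / d.
#' @param F polysome intensity (a.u., > 0)
#' @param F0 single-peptide intensity (a.u., > 0)
#' @param L1,L2 construct lengths in codons
#' @return list of class \code{OccupancyResult}: \code{d},
#'   \code{ribosomes_per_mrna}, \code{nt_per_ribosome},
#'   \code{sub_polysome} (TRUE when fewer than one ribosome per mRNA)
#' @export
ribosome_occupancy <- function(F, F0, L1, L2) {
  stopifnot(F > 0, F0 > 0, L1 > 0, L2 > 0)
  d <- F / (F0 * (L2 + 0.5 * L1))
  res <- list(d = d,
              ribosomes_per_mrna = d * (L1 + L2),
              nt_per_ribosome = 3 / d,
              sub_polysome = d * (L1 + L2) < 1)
  class(res) <- "OccupancyResult"
  res
}

#' Single mature-peptide intensity from a mixed amplitude sample
#'
#' Separates single released peptides from polysomes in a focus-amplitude
#' sample by a two-component Gaussian mixture (\code{mclust}); F0 is the
#' median of the observations assigned to the lower-intensity component.
#' Signals an error when the sample supports only one component, and
#' warns when the component means are separated by less than twice the
#' larger component spread.
#' @param amplitudes numeric vector of focus amplitudes
#' @return list: \code{F0}, \code{separation_ok}, \code{fit} (Mclust)
#' @importFrom mclust Mclust mclustBIC
#' @export
estimate_single_peptide_intensity <- function(amplitudes) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  stopifnot(length(amplitudes) >= 2L)
  if (stats::sd(amplitudes) == 0) {
    return(list(F0 = amplitudes[1], separation_ok = TRUE, fit = NULL))
  }
  fit <- tryCatch(Mclust(amplitudes, G = 1:2, verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(fit) || fit$G < 2L) {
    stop("amplitude sample is unimodal: single-peptide and polysome ",
         "populations are inseparable")
  }
  means <- fit$parameters$mean
  sds <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sds) == 1L) sds <- rep(sds, 2L)
  low <- which.min(means)
  sep_ok <- abs(diff(means)) >= 2 * max(sds)
  if (!sep_ok) {
    warning("mixture components poorly separated; F0 may be unreliable")
  }
  F0 <- stats::median(amplitudes[fit$classification == low])
  list(F0 = F0, separation_ok = sep_ok, fit = fit)
}

#' Integrated-intensity FRAP curve from a movie ROI
#'
#' Sums the intensity inside a fixed region of interest per frame and
#' normalizes so the prebleach mean is exactly 1.
#' @param movie 4D array [z, y, x, frame]
#' @param roi logical 3D array (same spatial shape) marking the ROI
#' @param prebleach_frames frames acquired before the bleach (>= 1)
#' @return \code{\link{frap_curve}} (arbitrary 1-second frame times
#'   unless \code{frame_interval} is given)
#' @param frame_interval seconds per frame
#' @export
frap_region_curve <- function(movie, roi, prebleach_frames,
                              frame_interval = 1) {
  stopifnot(length(dim(movie)) == 4L, is.logical(roi),
            all(dim(roi) == dim(movie)[1:3]), prebleach_frames >= 1L)
  if (!any(roi)) stop("ROI is empty or outside the image")
  nf <- dim(movie)[4]
  intensity <- vapply(seq_len(nf),
                      function(f) sum(movie[, , , f][roi]), 0)
  intensity <- intensity / mean(intensity[seq_len(prebleach_frames)])
  frap_curve((seq_len(nf) - 1L) * frame_interval, intensity,
             bleach_index = prebleach_frames + 1L,
             prebleach_frames = prebleach_frames)
}
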