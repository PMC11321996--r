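#' Call translating mRNAs by RNA-protein co-localization
#'
#' One-to-one greedy matching of mRNA and nascent-protein foci: all
#' candidate pairs within \code{max_dist} (closed bound: exactly 400 nm
#' matches) are sorted by ascending 3D distance and accepted when both
#' partners are still free. An mRNA with a matched protein focus is
#' called translating. An optimal (Hungarian-style) assignment is
#' available behind \code{method = "optimal"} for comparison; it
#' minimizes the total matched distance over a maximum matching.
#'
#' @param rna,protein spot data.frames with spot_id, z_nm, y_nm, x_nm
#' @param max_dist co-localization radius, nm
#' @param method \code{"greedy"} (default, deterministic; ties broken by
#'   lower rna then protein id) or \code{"optimal"}
#' @return data.frame of class \code{TranslationCall} rows:
#'   rna_spot_id, protein_spot_id (NA when unmatched), pair_distance_nm,
#'   translating
#' @export
match_spots <- function(rna, protein, max_dist = 400,
                        method = c("greedy", "optimal")) {
  method <- match.arg(method)
  nr <- nrow(rna); np <- nrow(protein)
  out <- data.frame(rna_spot_id = rna$spot_id,
                    protein_spot_id = rep(NA_integer_, nr),
                    pair_distance_nm = rep(NA_real_, nr),
                    translating = rep(FALSE, nr))
  if (nr == 0L || np == 0L) return(out)
  d2 <- outer(rna$z_nm, protein$z_nm, "-")^2 +
    outer(rna$y_nm, protein$y_nm, "-")^2 +
    outer(rna$x_nm, protein$x_nm, "-")^2
  cand <- which(d2 <= max_dist^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(out)
  dist <- sqrt(d2[cand])
  ord <- order(dist, cand[, 1], cand[, 2])
  if (method == "greedy") {
    rna_free <- rep(TRUE, nr); prot_free <- rep(TRUE, np)
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (rna_free[i] && prot_free[j]) {
        out$protein_spot_id[i] <- protein$spot_id[j]
        out$pair_distance_nm[i] <- dist[k]
        out$translating[i] <- TRUE
        rna_free[i] <- FALSE; prot_free[j] <- FALSE
      }
    }
  } else {
    # maximum bipartite matching minimizing total distance, via igraph's
    # weighted bipartite matching on transformed weights (large constant
    # minus distance favours both more pairs and shorter ones)
    g <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, nr), rep(TRUE, np)), edges = integer())
    big <- 10 * max_dist
    g <- igraph::add_edges(g, t(cbind(cand[, 1], nr + cand[, 2])),
                           weight = big - dist)
    mm <- igraph::max_bipartite_match(g)$matching
    for (i in seq_len(nr)) {
      j <- mm[i] - nr
      if (!is.na(j) && j >= 1L) {
        out$protein_spot_id[i] <- protein$spot_id[j]
        out$pair_distance_nm[i] <-
          sqrt(d2[i, j])
        out$translating[i] <- TRUE
      }
    }
  }
  out
}

#' Translating fraction of mRNA foci
#'
#' Fraction of mRNA foci with a matched protein focus, optionally
#' restricted to a subset of mRNA spot ids (e.g. a region mask applied
#' to centroids).
#' @param calls from \code{\link{match_spots}}
#' @param subset_ids optional rna_spot_id subset defining the region
#' @return list: \code{fraction}, \code{n_translating}, \code{n_total}
#' @export
translating_fraction <- function(calls, subset_ids = NULL) {
  if (!is.null(subset_ids)) {
    calls <- calls[calls$rna_spot_id %in% subset_ids, , drop = FALSE]
  }
  if (nrow(calls) == 0L) stop("no mRNA foci in the requested region")
  list(fraction = mean(calls$translating),
       n_translating = sum(calls$translating),
       n_total = nrow(calls))
}

#' Translating fraction per signed-distance bin
#'
#' Joins translation calls with signed-distance records (shared
#' rna/spot id), drops excluded records, bins the signed distance and
#' reports the translating fraction with numerator and denominator per
#' bin. Bins with fewer than \code{min_n} mRNAs are flagged.
#' @param calls from \code{\link{match_spots}}
#' @param records from \code{\link{signed_distances}} (spot_id matches
#'   rna_spot_id)
#' @param bin_edges ascending bin edges in nm (bins are left-closed)
#' @param min_n flag threshold for sparse bins
#' @return data.frame: bin_lo, bin_hi, n_translating, n_total, fraction,
#'   low_n
#' @export
fraction_by_distance_bin <- function(calls, records, bin_edges,
                                     min_n = 10L) {
  stopifnot(!is.unsorted(bin_edges), length(bin_edges) >= 2L)
  m <- merge(calls, records[!records$excluded,
                            c("spot_id", "signed_distance_nm")],
             by.x = "rna_spot_id", by.y = "spot_id")
  bins <- cut(m$signed_distance_nm, breaks = bin_edges, right = FALSE,
              include.lowest = FALSE)
  n_tot <- tapply(m$translating, bins, length)
  n_tr <- tapply(m$translating, bins, sum)
  n_tot[is.na(n_tot)] <- 0L
  n_tr[is.na(n_tr)] <- 0L
  data.frame(bin_lo = bin_edges[-length(bin_edges)],
             bin_hi = bin_edges[-1],
             n_translating = as.integer(n_tr),
             n_total = as.integer(n_tot),
             fraction = ifelse(n_tot > 0, n_tr / n_tot, NA_real_),
             low_n = n_tot < min_n)
}

#' Two-tailed Welch's t-test between two groups
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom (via \code{stats::t.test}). The degenerate case of two
#' zero-variance samples with equal means returns t = 0, p = 1 by
#' convention; zero-variance samples with different means return p = 0
#' with infinite t.
#' @param values_a,values_b numeric samples (n >= 2 each)
#' @return list of class \code{GroupComparison}: \code{t_statistic},
#'   \code{welch_df}, \code{p_value}, \code{mean_a}, \code{mean_b},
#'   \code{n_a}, \code{n_b}
#' @export
compare_groups_welch <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    res <- list(t_statistic = if (equal) 0 else sign(mean(values_a) -
                                                      mean(values_b)) * Inf,
                welch_df = length(values_a) + length(values_b) - 2,
                p_value = if (equal) 1 else 0)
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    res <- list(t_statistic = unname(tt$statistic),
                welch_df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  res$mean_a <- mean(values_a); res$mean_b <- mean(values_b)
  res$n_a <- length(values_a); res$n_b <- length(values_b)
  class(res) <- "GroupComparison"
  res
}

#' Replicate-level (superplot) intensity comparison
#'
#' Summarizes per-spot intensities to one mean per biological replicate
#' and compares the two regions on the replicate means (not the pooled
#' spots), avoiding pseudo-replication.
#' @param intensities numeric per-spot values
#' @param replicate replicate (e.g. embryo) label per spot
#' @param region region label per spot; exactly two regions required
#' @return list: \code{replicate_means} (data.frame region, replicate,
#'   mean_intensity, n_spots), \code{comparison}
#'   (\code{\link{compare_groups_welch}} on the replicate means)
#' @export
superplot_summary <- function(intensities, replicate, region) {
  stopifnot(length(intensities) == length(replicate),
            length(intensities) == length(region))
  regions <- sort(unique(region))
  if (length(regions) != 2L) stop("exactly two regions are required")
  df <- data.frame(intensity = intensities, replicate = replicate,
                   region = region)
  agg <- stats::aggregate(intensity ~ region + replicate, df, mean)
  cnt <- stats::aggregate(intensity ~ region + replicate, df, length)
  agg$n_spots <- cnt$intensity
  names(agg)[names(agg) == "intensity"] <- "mean_intensity"
  a <- agg$mean_intensity[agg$region == regions[1]]
  b <- agg$mean_intensity[agg$region == regions[2]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("at least two replicates per region are required")
  }
  list(replicate_means = agg, comparison = compare_groups_welch(a, b))
}
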