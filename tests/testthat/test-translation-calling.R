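spot_df <- function(pos) {
  pos <- matrix(pos, ncol = 3)
  data.frame(spot_id = seq_len(nrow(pos)), z_nm = pos[, 1],
             y_nm = pos[, 2], x_nm = pos[, 3])
}

test_that("the 400 nm rule is a closed bound", {
  rna <- spot_df(c(1000, 1000, 1000))
  expect_true(match_spots(rna, spot_df(c(1000, 1000, 1100)))$translating)
  expect_true(match_spots(rna, spot_df(c(1000, 1000, 1400)))$translating)
  expect_false(match_spots(rna, spot_df(c(1000, 1000, 1401)))$translating)
  # an unmatched RNA keeps NA partner fields
  call <- match_spots(rna, spot_df(c(1000, 1000, 1401)))
  expect_true(is.na(call$protein_spot_id))
  expect_true(is.na(call$pair_distance_nm))
})

test_that("greedy matching is one-to-one and distance-ordered", {
  # two RNAs compete for one protein: the closer RNA wins
  rna <- spot_df(rbind(c(0, 0, 0), c(0, 0, 300)))
  prot <- spot_df(c(0, 0, 120))
  calls <- match_spots(rna, prot)
  expect_equal(calls$translating, c(TRUE, FALSE))
  # each protein appears in at most one call
  set.seed(1)
  rna <- spot_df(cbind(runif(60, 0, 3000), runif(60, 0, 3000),
                       runif(60, 0, 3000)))
  prot <- spot_df(cbind(runif(40, 0, 3000), runif(40, 0, 3000),
                        runif(40, 0, 3000)))
  calls <- match_spots(rna, prot)
  matched <- calls$protein_spot_id[!is.na(calls$protein_spot_id)]
  expect_equal(length(matched), length(unique(matched)))
  expect_true(all(calls$pair_distance_nm <= 400, na.rm = TRUE))
})

test_that("greedy and optimal matching agree on generic inputs", {
  set.seed(21)
  rna <- spot_df(cbind(runif(50, 0, 4000), runif(50, 0, 4000),
                       runif(50, 0, 4000)))
  prot <- spot_df(cbind(runif(30, 0, 4000), runif(30, 0, 4000),
                        runif(30, 0, 4000)))
  g <- match_spots(rna, prot, method = "greedy")
  o <- match_spots(rna, prot, method = "optimal")
  # the optimal matching can only match at least as many pairs
  expect_gte(sum(o$translating), sum(g$translating))
  expect_gt(sum(g$translating & o$translating),
            0.8 * sum(g$translating))
})

test_that("matching is role-symmetric on generic inputs", {
  set.seed(33)
  a <- spot_df(cbind(runif(40, 0, 3000), runif(40, 0, 3000),
                     runif(40, 0, 3000)))
  b <- spot_df(cbind(runif(40, 0, 3000), runif(40, 0, 3000),
                     runif(40, 0, 3000)))
  ab <- match_spots(a, b)
  ba <- match_spots(b, a)
  pairs_ab <- sort(paste(ab$rna_spot_id[ab$translating],
                         ab$protein_spot_id[ab$translating]))
  pairs_ba <- sort(paste(ba$protein_spot_id[ba$translating],
                         ba$rna_spot_id[ba$translating]))
  expect_equal(pairs_ab, pairs_ba)
})

test_that("translating fraction is recovered on phantoms", {
  cfg <- phantom_config(seed = 41, n_rna_spots = 1000,
                        translating_fraction = 0.4, n_granules = 0,
                        placement_law = placement_uniform_volume(),
                        shape_zyx = c(24, 256, 256))
  ph <- generate_phantom(cfg, render = FALSE)
  calls <- match_spots(ph$truth$rna, ph$truth$protein)
  est <- translating_fraction(calls)
  expect_equal(est$n_total, 1000)
  expect_lt(abs(est$fraction - 0.4), 0.05)
  # calls agree with ground-truth labels almost everywhere
  expect_gt(mean(calls$translating == ph$truth$rna$translating), 0.99)
})

test_that("whole-image fraction is the count-weighted mean over regions", {
  set.seed(5)
  calls <- data.frame(rna_spot_id = 1:200,
                      protein_spot_id = NA_integer_,
                      pair_distance_nm = NA_real_,
                      translating = runif(200) < 0.3)
  region_a <- 1:70
  region_b <- 71:200
  fa <- translating_fraction(calls, region_a)
  fb <- translating_fraction(calls, region_b)
  f <- translating_fraction(calls)
  expect_equal(f$fraction,
               (fa$fraction * fa$n_total + fb$fraction * fb$n_total) /
                 f$n_total)
  expect_error(translating_fraction(calls, subset_ids = 1000), "no mRNA")
})

test_that("per-bin fractions separate surface and interior populations", {
  # constructed truth: all spots outside the granule translate, none
  # inside do
  records <- data.frame(spot_id = 1:400,
                        signed_distance_nm = c(runif(200, 0, 200),
                                               runif(200, -200, 0)),
                        excluded = FALSE)
  calls <- data.frame(rna_spot_id = 1:400,
                      protein_spot_id = c(1:200, rep(NA, 200)),
                      pair_distance_nm = NA_real_,
                      translating = rep(c(TRUE, FALSE), each = 200))
  fb <- fraction_by_distance_bin(calls, records,
                                 bin_edges = seq(-200, 200, by = 25))
  expect_true(all(fb$fraction[fb$bin_lo >= 0] == 1))
  expect_true(all(fb$fraction[fb$bin_hi <= 0] == 0))
  # pooled fraction equals the denominator-weighted mean over bins
  expect_equal(sum(fb$fraction * fb$n_total) / sum(fb$n_total),
               mean(calls$translating))
  # excluded records do not contribute
  records$excluded[1:50] <- TRUE
  fb2 <- fraction_by_distance_bin(calls, records, seq(-200, 200, by = 25))
  expect_equal(sum(fb2$n_total), 350)
})

test_that("Welch comparison matches the textbook formulas", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  res <- compare_groups_welch(a, b)
  # hand calculation: se^2 = va/4 + vb/4, t = -1/se, Welch df
  va <- var(a); vb <- var(b)
  se2 <- va / 4 + vb / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((va / 4)^2 / 3 + (vb / 4)^2 / 3)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(res$t_statistic, t_hand)
  expect_equal(res$welch_df, df_hand)
  expect_equal(res$p_value, p_hand)
  expect_gt(res$welch_df, min(length(a), length(b)) - 1)
  expect_lte(res$welch_df, length(a) + length(b) - 2)
})

test_that("degenerate Welch inputs follow the stated conventions", {
  res <- compare_groups_welch(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- compare_groups_welch(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$t_statistic, 0)
  expect_equal(res2$p_value, 1)
})

test_that("superplot comparison works on replicate means, not spots", {
  set.seed(8)
  # three embryos per region; germplasm-like has a big per-spot n
  df <- expand.grid(rep = 1:3, region = c("germplasm", "soma"))
  spots <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    n <- if (df$region[i] == "germplasm") 200 else 20
    data.frame(intensity = rnorm(n, 100, 10), replicate = df$rep[i],
               region = df$region[i])
  }))
  res <- superplot_summary(spots$intensity, spots$replicate, spots$region)
  expect_equal(nrow(res$replicate_means), 6)
  # each replicate mean equals the arithmetic mean of its spots
  for (i in seq_len(6)) {
    rm <- res$replicate_means[i, ]
    sel <- spots$replicate == rm$replicate & spots$region == rm$region
    expect_equal(rm$mean_intensity, mean(spots$intensity[sel]))
  }
  expect_equal(res$comparison$n_a, 3)
  # identical replicate means give p = 1
  df2 <- data.frame(intensity = rep(c(1, 2), each = 4),
                    replicate = rep(1:4, 2),
                    region = rep(c("a", "b"), each = 4))
  # per-replicate means are 1 (region a) and 2 (region b): zero variance,
  # unequal means -> p = 0; equal constructed means -> p = 1
  res2 <- superplot_summary(df2$intensity, df2$replicate, df2$region)
  expect_equal(res2$comparison$p_value, 0)
  df3 <- data.frame(intensity = rep(1, 8), replicate = rep(1:4, 2),
                    region = rep(c("a", "b"), each = 4))
  res3 <- superplot_summary(df3$intensity, df3$replicate, df3$region)
  expect_equal(res3$comparison$p_value, 1)
  # a single replicate is refused
  expect_error(superplot_summary(1:4, rep(1, 4), rep(c("a", "b"), 2)),
               "replicates")
})
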