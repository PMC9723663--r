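test_that("Bray-Curtis similarity matches its closed form", {
  expect_equal(bray_curtis_similarity(c(2, 3, 1), c(2, 3, 1)), 1)
  expect_equal(bray_curtis_similarity(c(1, 0, 0), c(0, 2, 3)), 0)
  expect_equal(bray_curtis_similarity(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_warning(s <- bray_curtis_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_true(is.na(s))
  # joint rescaling invariance
  set.seed(31)
  x <- runif(10); y <- runif(10)
  expect_equal(bray_curtis_similarity(x, y),
               bray_curtis_similarity(7 * x, 7 * y), tolerance = 1e-12)
  # agrees with the standard distance implementation
  expect_equal(bray_curtis_similarity(x, y),
               1 - as.numeric(vegan::vegdist(rbind(x, y), "bray")),
               tolerance = 1e-12)
})

test_that("lag pairs pool by austral season blocks", {
  md <- data.frame(sample_id = c("s1", "s2", "s3", "s4", "s5"),
                   year = c(2015, 2015, 2015, 2016, 2015),
                   month = c(3, 9, 4, 10, 5))
  set.seed(32)
  counts <- matrix(rpois(25, 20), 5,
                   dimnames = list(md$sample_id, paste0("f", 1:5)))
  pr <- build_lag_pairs(counts, md)
  get <- function(a, b) pr[pr$sample_i %in% c(a, b) &
                             pr$sample_j %in% c(a, b), ]
  # Mar 2015 vs Sep 2015: lag 6, cross-season
  expect_equal(get("s1", "s2")$lag_months, 6)
  expect_equal(get("s1", "s2")$pool, "cross_season")
  # Sep 2015 vs Oct 2016: same season type, different blocks
  expect_equal(get("s2", "s4")$lag_months, 13)
  expect_equal(get("s2", "s4")$pool, "same_season_cross_year")
  # Apr 2015 vs May 2015: same Autumn-Winter block, excluded from pools
  expect_equal(get("s3", "s5")$pool, "excluded")
  expect_true(isTRUE(attr(pr, "underpowered")) ||
                nrow(pr) >= 8)   # 10 pairs here, so not underpowered
})

test_that("Oct 2015 vs Oct 2016 is a 12-month same-season pair", {
  md <- data.frame(sample_id = c("a", "b"),
                   year = c(2015, 2016), month = c(10, 10))
  counts <- matrix(c(5, 1, 1, 5), 2,
                   dimnames = list(c("a", "b"), c("f1", "f2")))
  pr <- build_lag_pairs(counts, md)
  expect_equal(pr$lag_months, 12)
  expect_equal(pr$pool, "same_season_cross_year")
  expect_true(attr(pr, "underpowered"))
})

test_that("seasonal shift test handles identical pools and empty pools", {
  pr <- data.frame(sample_i = "a", sample_j = "b", lag_months = 6,
                   similarity = 0.5, season_i = "AW", season_j = "SS",
                   pool = "cross_season")
  r <- seasonal_shift_test(pr)
  expect_false(r$evaluable)
  # identical similarities in both pools -> H = 0, p = 1, not seasonal
  pr2 <- data.frame(sample_i = letters[1:6], sample_j = letters[7:12],
                    lag_months = c(6, 6, 6, 12, 12, 12),
                    similarity = rep(0.4, 6),
                    season_i = "AW", season_j = "AW",
                    pool = rep(c("cross_season", "same_season_cross_year"),
                               each = 3))
  r2 <- seasonal_shift_test(pr2)
  expect_equal(r2$H, 0)
  expect_equal(r2$p, 1)
  expect_false(r2$seasonal)
  expect_true(r2$degenerate)
})

test_that("a strongly seasonal synthetic site is detected, a flat one not", {
  sim <- generate_time_series(simulation_config(
    n_sites = 1, months = 60, n_bact_asvs = 20, n_phyto_asvs = 10,
    seasonal_amplitude = 1.5, library_size = 2000, seed = 33))
  res <- site_seasonality(sim$bact, sim$metadata,
                          analysis_config(top_k = 20))
  expect_true(res[[1]]$report$seasonal)
  expect_gt(res[[1]]$report$mean_same, res[[1]]$report$mean_cross)

  sim0 <- generate_time_series(simulation_config(
    n_sites = 1, months = 60, n_bact_asvs = 20, n_phyto_asvs = 10,
    seasonal_amplitude = 0, library_size = 2000, seed = 34))
  res0 <- site_seasonality(sim0$bact, sim0$metadata,
                           analysis_config(top_k = 20))
  expect_false(res0[[1]]$report$seasonal)
})

test_that("seasonality decision is invariant to sample input order", {
  sim <- generate_time_series(simulation_config(
    n_sites = 1, months = 40, n_bact_asvs = 15, n_phyto_asvs = 10,
    seasonal_amplitude = 1.2, library_size = 2000, seed = 35))
  md <- sim$metadata
  perm <- sample(nrow(md))
  r1 <- site_seasonality(sim$bact, md, analysis_config(top_k = 15))
  r2 <- site_seasonality(sim$bact[perm, ], md[perm, ],
                         analysis_config(top_k = 15))
  expect_equal(r1[[1]]$report$H, r2[[1]]$report$H, tolerance = 1e-12)
  expect_equal(r1[[1]]$report$seasonal, r2[[1]]$report$seasonal)
})

test_that("Mantel correlogram finds the 12-month cycle structure", {
  sim <- generate_time_series(simulation_config(
    n_sites = 1, months = 60, n_bact_asvs = 20, n_phyto_asvs = 10,
    seasonal_amplitude = 1.5, library_size = 2000, seed = 36))
  feats <- top_features(sim$bact, 20)
  mc <- mantel_correlogram(sim$bact[, feats], sim$metadata,
                           n_perm = 999, seed = 2)
  r6 <- mc[mc$lag_class == 6, ]
  r12 <- mc[mc$lag_class == 12, ]
  expect_lt(r6$r, 0)
  expect_gt(r12$r, 0)
  expect_lt(r6$p_corrected, 0.05)
  expect_lt(r12$p_corrected, 0.05)
  # the per-class statistic agrees with the standard implementation
  md <- sim$metadata
  mt <- 12 * md$year + (md$month - 1)
  d <- vegan::vegdist(relative_abundance(sim$bact[md$sample_id, feats]),
                      "bray")
  veg <- suppressWarnings(vegan::mantel.correlog(
    d, D.geo = dist(mt), break.pts = seq(0.5, 14.5, 1), cutoff = FALSE,
    nperm = 0))
  vr <- veg$mantel.res[, "Mantel.cor"]
  expect_equal(unname(vr[1:14]), mc$r[1:14], tolerance = 1e-9)
})

test_that("a community identical in every sample degenerates cleanly", {
  counts <- matrix(rep(c(10L, 5L, 1L), each = 12), 12,
                   dimnames = list(sprintf("s%02d", 1:12), c("a", "b", "c")))
  md <- data.frame(sample_id = rownames(counts),
                   year = 2015, month = 1:12)
  mc <- mantel_correlogram(counts, md, n_perm = 49, seed = 1)
  expect_s3_class(mc, "degenerate_correlogram")
})

test_that("shuffled month labels yield a calibrated correlogram null", {
  hits <- 0; total <- 0
  for (s in 1:200) {
    set.seed(4000 + s)
    counts <- matrix(rnbinom(36 * 12, mu = 50, size = 2), 36,
                     dimnames = list(sprintf("s%02d", 1:36), NULL))
    colnames(counts) <- paste0("f", 1:12)
    md <- data.frame(sample_id = rownames(counts),
                     year = rep(2015:2017, each = 12), month = rep(1:12, 3))
    mc <- mantel_correlogram(counts, md, n_perm = 99, seed = s)
    hits <- hits + sum(mc$p < 0.05)
    total <- total + nrow(mc)
  }
  expect_lte(hits / total, 0.07)
})
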