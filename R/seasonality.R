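#' Bray--Curtis similarity of two abundance vectors
#'
#' `1 - sum(|x - y|) / sum(x + y)`; the community-turnover currency of the
#' time-lag analysis. Invariant to joint rescaling of both vectors.
#'
#' @param x,y Equal-length non-negative vectors.
#' @return Similarity in `[0, 1]`, or `NA` (flagged with a warning) when
#'   both vectors are all zero; such pairs are excluded downstream.
#' @export
bray_curtis_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) {
    warning("Bray-Curtis undefined for two all-zero vectors")
    return(NA_real_)
  }
  1 - sum(abs(x - y)) / tot
}

#' Within-site time-lag pairs with season pooling
#'
#' Builds all unordered within-site sample pairs, computes their
#' Bray--Curtis similarity on relative abundances of the supplied feature
#' subset, the lag in whole months, and the season pool: `cross_season`
#' when the two samples fall in different austral season types,
#' `same_season_cross_year` when they share a season type but belong to
#' different season-block instances, and `excluded` for pairs inside one
#' block (still usable in the correlogram).
#'
#' @param counts Count matrix (samples x features) for one site, restricted
#'   to the feature subset of interest.
#' @param metadata Data frame with `sample_id`, `year`, `month` covering the
#'   rows of `counts`.
#' @param config An [analysis_config()] (supplies the season month sets).
#' @return Data frame of lag pairs: `sample_i`, `sample_j`, `lag_months`,
#'   `similarity`, `season_i`, `season_j`, `pool`. Attribute
#'   `"underpowered"` is `TRUE` when fewer than 8 pairs exist.
#' @export
build_lag_pairs <- function(counts, metadata, config = analysis_config()) {
  ids <- metadata$sample_id
  if (length(ids) < 2) stop("need >= 2 samples at the site")
  if (!all(ids %in% rownames(counts)))
    stop("metadata samples missing from counts: ",
         paste(setdiff(ids, rownames(counts)), collapse = ", "))
  ra <- relative_abundance(counts[ids, , drop = FALSE])
  mt <- 12 * metadata$year + (metadata$month - 1)
  season <- season_of_month(metadata$month, config)
  block <- season_block_id(metadata$year, metadata$month, config)

  idx <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  sim <- vapply(seq_len(nrow(idx)), function(r)
    suppressWarnings(bray_curtis_similarity(ra[i[r], ], ra[j[r], ])),
    numeric(1))
  pool <- ifelse(season[i] != season[j], "cross_season",
                 ifelse(block[i] != block[j], "same_season_cross_year",
                        "excluded"))
  out <- data.frame(sample_i = ids[i], sample_j = ids[j],
                    lag_months = abs(mt[j] - mt[i]),
                    similarity = sim,
                    season_i = season[i], season_j = season[j],
                    pool = pool, stringsAsFactors = FALSE)
  out <- out[out$lag_months >= 1 & !is.na(out$similarity), , drop = FALSE]
  attr(out, "underpowered") <- nrow(out) < 8
  out
}

#' Mantel correlogram of community dissimilarity over time lags
#'
#' Per lag class, the normalised Mantel statistic between the Bray--Curtis
#' dissimilarity matrix and the lag-class membership indicator (sign
#' convention: positive r means samples within the class are more similar
#' than average, as in the standard correlogram), with a two-tailed
#' permutation p-value from joint row/column shuffles and progressive
#' Bonferroni adjustment across classes.
#'
#' @param counts Count matrix (samples x features) for one site.
#' @param metadata Data frame with `sample_id`, `year`, `month`.
#' @param lag_breaks Optional vector of lag classes in whole months;
#'   defaults to monthly classes up to half the series span.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation test.
#' @return Data frame of class `"mantel_correlogram"` with columns
#'   `lag_class`, `n_pairs`, `r`, `p`, `p_corrected`. Classes with fewer
#'   than 5 pairs keep their r but are flagged via the
#'   `"unreliable_classes"` attribute. A community identical in every
#'   sample returns a `"degenerate_correlogram"` marker object.
#' @export
mantel_correlogram <- function(counts, metadata, lag_breaks = NULL,
                               n_perm = 999, seed = 1) {
  ids <- metadata$sample_id
  ra <- relative_abundance(counts[ids, , drop = FALSE])
  dmat <- as.matrix(vegan::vegdist(ra, method = "bray"))
  dv <- as.dist(dmat)
  if (all(dv == 0)) {
    out <- list(degenerate = TRUE)
    class(out) <- "degenerate_correlogram"
    return(out)
  }
  mt <- 12 * metadata$year + (metadata$month - 1)
  lag <- as.dist(abs(outer(mt, mt, "-")))
  span <- max(mt) - min(mt)
  if (is.null(lag_breaks)) lag_breaks <- seq_len(floor(span / 2))

  dvec <- as.numeric(dv)
  M <- length(dvec)
  mean_d <- mean(dvec); sd_d <- sd(dvec)
  idx <- lapply(lag_breaks, function(k) which(as.numeric(lag) == k))
  m_k <- lengths(idx)
  keep <- m_k > 0
  lag_breaks <- lag_breaks[keep]; idx <- idx[keep]; m_k <- m_k[keep]
  sd_iv <- sqrt(m_k * (1 - m_k / M) / (M - 1))
  r_of <- function(v) {
    s_in <- vapply(idx, function(ii) sum(v[ii]), numeric(1))
    ## Pearson correlation with the binary in-class indicator, negated so
    ## that positive r = within-class similarity
    -((s_in - m_k * mean_d) / (M - 1)) / (sd_d * sd_iv)
  }
  r_obs <- r_of(dvec)
  set.seed(seed)
  n <- nrow(dmat)
  exceed <- numeric(length(idx))
  for (b in seq_len(n_perm)) {
    pp <- sample.int(n)
    vperm <- as.numeric(as.dist(dmat[pp, pp]))
    exceed <- exceed + (abs(r_of(vperm)) >= abs(r_obs) - 1e-12)
  }
  p <- (1 + exceed) / (n_perm + 1)
  p_corr <- pmin(1, p * seq_along(p))      # progressive Bonferroni
  out <- data.frame(lag_class = lag_breaks, n_pairs = m_k,
                    r = r_obs, p = p, p_corrected = p_corr)
  attr(out, "unreliable_classes") <- lag_breaks[m_k < 5]
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}

#' Season-interval seasonality test
#'
#' Compares pooled Bray--Curtis similarities of cross-season pairs
#' (6-month-type intervals, e.g. Spring--Summer vs Autumn--Winter) against
#' same-season cross-year pairs (12-month-type intervals, e.g.
#' Spring--Summer vs Spring--Summer) with a tie-corrected Kruskal--Wallis
#' test. A site is seasonal when the Bonferroni-adjusted q is below alpha
#' and same-season pairs are on average more similar than cross-season
#' pairs.
#'
#' @param pairs Lag pairs from [build_lag_pairs()].
#' @param alpha Significance level (default 0.05).
#' @param n_sites_for_bonferroni Number of sites tested in the study; the
#'   per-site p is multiplied by this (capped at 1).
#' @param site Optional site label carried into the report.
#' @return List of class `"seasonality_report"`: `site`, `n_cross`,
#'   `n_same`, `mean_cross`, `mean_same`, `H`, `p`, `q`, `seasonal`,
#'   `evaluable`, `degenerate`, `underpowered`.
#' @export
seasonal_shift_test <- function(pairs, alpha = 0.05,
                                n_sites_for_bonferroni = 1, site = NA) {
  cross <- pairs$similarity[pairs$pool == "cross_season"]
  same <- pairs$similarity[pairs$pool == "same_season_cross_year"]
  rep0 <- list(site = site, n_cross = length(cross), n_same = length(same),
               mean_cross = mean(cross), mean_same = mean(same),
               H = NA_real_, p = NA_real_, q = NA_real_,
               seasonal = FALSE, evaluable = TRUE, degenerate = FALSE,
               underpowered = isTRUE(attr(pairs, "underpowered")))
  if (length(cross) == 0 || length(same) == 0) {
    rep0$evaluable <- FALSE
    class(rep0) <- "seasonality_report"
    return(rep0)
  }
  vals <- c(cross, same)
  if (length(unique(vals)) < 2) {          # all similarities tied
    rep0$H <- 0; rep0$p <- 1; rep0$q <- 1; rep0$degenerate <- TRUE
    class(rep0) <- "seasonality_report"
    return(rep0)
  }
  g <- factor(rep(c("cross", "same"), c(length(cross), length(same))))
  kw <- kruskal.test(vals, g)
  rep0$H <- unname(kw$statistic)
  rep0$p <- kw$p.value
  rep0$q <- min(1, kw$p.value * n_sites_for_bonferroni)
  rep0$seasonal <- rep0$q < alpha && rep0$mean_same > rep0$mean_cross
  class(rep0) <- "seasonality_report"
  rep0
}

#' Per-site seasonality analysis
#'
#' Restricts a count table to its top-k most abundant features, builds
#' within-site lag pairs and runs the season-interval test per site,
#' Bonferroni-correcting over the number of sites tested.
#'
#' @param counts Count matrix covering all sites.
#' @param metadata Data frame with `sample_id`, `site`, `year`, `month`.
#' @param config An [analysis_config()] (`top_k`, `alpha`, season sets).
#' @param correlogram If `TRUE`, also compute a Mantel correlogram per site.
#' @param n_perm,seed Permutation settings for the correlogram.
#' @return Named list of per-site results, each with `pairs`, `report`, and
#'   optionally `correlogram`.
#' @export
site_seasonality <- function(counts, metadata, config = analysis_config(),
                             correlogram = FALSE, n_perm = 999, seed = 1) {
  feats <- top_features(counts, config$top_k)
  sites <- unique(metadata$site)
  out <- lapply(sites, function(s) {
    md <- metadata[metadata$site == s, , drop = FALSE]
    pr <- build_lag_pairs(counts[md$sample_id, feats, drop = FALSE], md,
                          config)
    res <- list(pairs = pr,
                report = seasonal_shift_test(
                  pr, config$alpha, n_sites_for_bonferroni = length(sites),
                  site = s))
    if (correlogram)
      res$correlogram <- mantel_correlogram(
        counts[md$sample_id, feats, drop = FALSE], md,
        n_perm = n_perm, seed = seed)
    res
  })
  names(out) <- sites
  out
}
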