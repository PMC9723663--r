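#' Per-sample relative abundance of a feature group
#'
#' @param counts Count matrix (samples x features).
#' @param members Feature names (subset of `colnames(counts)`).
#' @return Named numeric vector: 100 x member counts / sample total, per
#'   sample. Samples with zero total are returned as `NA` and flagged via
#'   the `"zero_samples"` attribute; an empty member set yields all zeros
#'   with a warning.
#' @export
group_relative_abundance <- function(counts, members) {
  counts <- as.matrix(counts)
  if (!all(members %in% colnames(counts)))
    stop("members must be a subset of the count table features")
  tot <- rowSums(counts)
  if (length(members) == 0) {
    warning("empty member set: relative abundance is 0 everywhere")
    out <- setNames(rep(0, nrow(counts)), rownames(counts))
    attr(out, "zero_samples") <- rownames(counts)[tot == 0]
    return(out)
  }
  num <- rowSums(counts[, members, drop = FALSE])
  out <- ifelse(tot == 0, NA_real_, 100 * num / tot)
  names(out) <- rownames(counts)
  attr(out, "zero_samples") <- rownames(counts)[tot == 0]
  out
}

anosim_r <- function(rank_d, groups, n) {
  within <- as.dist(outer(groups, groups, "==")) == 1
  rb <- mean(rank_d[!within]); rw <- mean(rank_d[within])
  (rb - rw) / (n * (n - 1) / 4)
}

# all distinct arrangements of a label multiset (for exact permutation p)
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(pool) {
    if (length(pool) == 0) return(list(character(0)))
    out <- list()
    for (u in unique(pool)) {
      rest <- pool[-match(u, pool)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(u, tail)
    }
    out
  }
  rec(sort(labels))
}

n_multiset_permutations <- function(labels) {
  tab <- table(labels)
  exp(lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between-group versus within-group
#' dissimilarities, `R = (mean between rank - mean within rank) / (M/2)`
#' with `M = n(n-1)/2` pairs, so `R` lies in `[-1, 1]`. The permutation p
#' is exact (full enumeration of distinct label arrangements) when their
#' number does not exceed `exact_limit`, otherwise estimated from `n_perm`
#' random label permutations. Pairwise group contrasts are
#' Bonferroni-corrected by the number of group pairs.
#'
#' @param d Dissimilarity matrix or `dist` object.
#' @param groups Group label per sample (>= 2 groups; singleton groups are
#'   excluded with a warning).
#' @param n_perm Random permutations when enumeration is infeasible.
#' @param seed Integer seed for random permutations.
#' @param exact_limit Maximum number of arrangements enumerated exactly.
#' @param pairwise Compute pairwise group contrasts.
#' @return List of class `"anosim_result"`: `R`, `p`, `exact`, `n_perm`,
#'   and `pairwise` (data frame with `group_a`, `group_b`, `R`, `p`, `q`).
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1, exact_limit = 20000,
                   pairwise = TRUE) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("one group label per sample required")
  keep_groups <- names(which(table(groups) >= 2))
  if (length(setdiff(unique(groups), keep_groups)) > 0) {
    warning("groups of size 1 excluded: ",
            paste(setdiff(unique(groups), keep_groups), collapse = ", "))
    sel <- groups %in% keep_groups
    d <- d[sel, sel, drop = FALSE]; groups <- groups[sel]
  }
  if (length(unique(groups)) < 2) stop("need >= 2 groups with >= 2 samples")
  n <- nrow(d)
  rank_d <- rank(as.dist(d))           # midranks
  r_obs <- anosim_r(rank_d, groups, n)

  exact <- n_multiset_permutations(groups) <= exact_limit
  if (exact) {
    perms <- multiset_permutations(groups)
    r_perm <- vapply(perms, function(g) anosim_r(rank_d, g, n), numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    np <- length(perms)
  } else {
    set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(i)
      anosim_r(rank_d, sample(groups), n), numeric(1))
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (n_perm + 1)
    np <- n_perm
  }

  pw <- NULL
  if (pairwise && length(unique(groups)) > 2) {
    gl <- sort(unique(groups))
    combos <- combn(gl, 2)
    n_comp <- ncol(combos)
    pw <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
      sel <- groups %in% combos[, i]
      sub <- anosim(d[sel, sel, drop = FALSE], groups[sel], n_perm = n_perm,
                    seed = seed + i, exact_limit = exact_limit,
                    pairwise = FALSE)
      data.frame(group_a = combos[1, i], group_b = combos[2, i],
                 R = sub$R, p = sub$p, q = min(1, sub$p * n_comp),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- list(R = r_obs, p = p, exact = exact, n_perm = np, pairwise = pw)
  class(out) <- "anosim_result"
  out
}

#' SIMPER: per-feature contributions to between-group dissimilarity
#'
#' Decomposes the average between-group Bray--Curtis dissimilarity into
#' per-feature contributions: for every between-group sample pair the
#' feature's share is `|x_f - y_f| / sum(x + y)`, averaged over pairs.
#' Contributions are non-negative and sum exactly to the average
#' between-group dissimilarity.
#'
#' @param counts Abundance matrix (samples x features); pass relative
#'   abundances to decompose the similarity scale used elsewhere.
#' @param groups Group label per sample; exactly two groups.
#' @return Data frame sorted by decreasing contribution: `feature`,
#'   `contribution`, `share` (fraction of the total), `cum_share`; the
#'   average between-group dissimilarity is attached as attribute
#'   `"total_dissimilarity"`.
#' @export
simper <- function(counts, groups) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 2) stop("simper requires exactly 2 groups")
  ia <- which(groups == gl[1]); ib <- which(groups == gl[2])
  if (length(ia) == 0 || length(ib) == 0) stop("empty group")
  nf <- ncol(counts)
  acc <- numeric(nf)
  npair <- 0L
  for (i in ia) for (j in ib) {
    tot <- sum(counts[i, ] + counts[j, ])
    if (tot == 0) next
    acc <- acc + abs(counts[i, ] - counts[j, ]) / tot
    npair <- npair + 1L
  }
  if (npair == 0) stop("no usable between-group pairs")
  contrib <- acc / npair
  total <- sum(contrib)
  ord <- order(-contrib, seq_len(nf))
  share <- if (total > 0) contrib / total else rep(0, nf)
  out <- data.frame(feature = colnames(counts)[ord],
                    contribution = contrib[ord],
                    share = share[ord],
                    cum_share = cumsum(share[ord]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "total_dissimilarity") <- total
  out
}

#' Homoscedasticity-gated univariate group comparison
#'
#' Levene's test (mean-centred) decides the branch: when group variances
#' are homogeneous (Levene p >= alpha) the groups are compared by one-way
#' ANOVA with Tukey--Kramer pairwise comparisons; otherwise by a
#' Kruskal--Wallis test with pairwise Wilcoxon rank-sum tests. Pairwise p
#' values are Bonferroni-corrected by the number of group pairs.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (>= 2 groups, each n >= 3).
#' @param alpha Significance level (used for the Levene gate and reported
#'   flags).
#' @return List of class `"group_comparison"`: `statistic` (name),
#'   `value`, `p`, `branch` (`"anova"` or `"kruskal"`), `levene_p`,
#'   `pairwise` (data frame: `group_a`, `group_b`, `p`, `q`,
#'   `significant`), `degenerate`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 3)) stop("each group needs n >= 3")
  if (length(unique(values)) < 2) {
    out <- list(statistic = NA_character_, value = NA_real_, p = NA_real_,
                branch = NA_character_, levene_p = NA_real_,
                pairwise = NULL, degenerate = TRUE)
    class(out) <- "group_comparison"
    return(out)
  }
  lev <- car::leveneTest(values, groups, center = mean)
  levene_p <- lev[["Pr(>F)"]][1]
  n_comp <- choose(nlevels(groups), 2)

  if (levene_p >= alpha) {
    fit <- aov(values ~ groups)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    f <- summary(fit)[[1]][["F value"]][1]
    tk <- TukeyHSD(fit)$groups
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    pw <- data.frame(group_a = vapply(pairs, `[`, "", 2),
                     group_b = vapply(pairs, `[`, "", 1),
                     p = tk[, "p adj"],
                     q = pmin(1, tk[, "p adj"] * n_comp),
                     stringsAsFactors = FALSE, row.names = NULL)
    out <- list(statistic = "ANOVA_F", value = unname(f), p = p,
                branch = "anova", levene_p = levene_p)
  } else {
    kw <- kruskal.test(values, groups)
    pwt <- pairwise.wilcox.test(values, groups, p.adjust.method = "none",
                                exact = FALSE)
    pm <- pwt$p.value
    rows <- list()
    for (i in rownames(pm)) for (j in colnames(pm))
      if (!is.na(pm[i, j]))
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = j, group_b = i, p = pm[i, j],
          q = min(1, pm[i, j] * n_comp), stringsAsFactors = FALSE)
    pw <- do.call(rbind, rows)
    out <- list(statistic = "KW_H", value = unname(kw$statistic),
                p = kw$p.value, branch = "kruskal", levene_p = levene_p)
  }
  pw$significant <- pw$q < alpha
  out$pairwise <- pw
  out$degenerate <- FALSE
  class(out) <- "group_comparison"
  out
}
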