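#' Per-sample relative abundances
#'
#' @param counts Numeric matrix, samples in rows, features in columns.
#' @return Matrix of the same shape with rows summing to 1. Rows with zero
#'   total are returned as all-zero and flagged via the `"zero_samples"`
#'   attribute.
#' @export
relative_abundance <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  zero <- tot == 0
  tot[zero] <- 1
  out <- counts / tot
  attr(out, "zero_samples") <- rownames(counts)[zero]
  out
}

#' Select the most abundant features
#'
#' Ranks features by mean relative abundance across all samples and returns
#' the names of the top `k`; ties are broken by column order.
#'
#' @param counts Count matrix, samples in rows.
#' @param k Number of features to keep.
#' @return Character vector of feature names (length `min(k, ncol)`).
#' @export
top_features <- function(counts, k = 50) {
  ra <- relative_abundance(counts)
  mu <- colMeans(ra)
  ord <- order(-mu, seq_along(mu))
  colnames(counts)[ord[seq_len(min(k, ncol(counts)))]]
}

#' Austral season of a calendar month
#'
#' @param month Integer month(s) 1--12.
#' @param config An [analysis_config()] supplying the season month sets.
#' @return `"AW"` (Autumn--Winter) or `"SS"` (Spring--Summer) per month.
#' @export
season_of_month <- function(month, config = analysis_config()) {
  out <- ifelse(month %in% config$season_aw, "AW",
                ifelse(month %in% config$season_ss, "SS", NA_character_))
  if (anyNA(out)) stop("month must be in 1..12")
  out
}

# Season-block instance id: AW blocks live within one calendar year;
# SS blocks (Sep..Feb) are labelled by the year of their September.
season_block_id <- function(year, month, config = analysis_config()) {
  s <- season_of_month(month, config)
  ifelse(s == "AW", year, ifelse(month >= 9, year, year - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
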