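#' Default alignment scoring for identity screening
#'
#' Match +2, mismatch -4, gap open -10, gap extension -1 -- the convention of
#' common greedy clustering tools.
#'
#' @export
screen_scoring <- function(match = 2, mismatch = -4,
                           gap_open = -10, gap_extend = -1) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

screen_submat <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch   # N never rewarded, even against N
  m
}

#' Pairwise global identity of two nucleotide sequences
#'
#' Identity is the number of matching columns divided by the number of
#' alignment columns of the optimal global (Needleman--Wunsch) alignment,
#' with terminal gap columns excluded from both counts. Ambiguity code N
#' aligns but never counts as a match.
#'
#' @param seq_a,seq_b Non-empty nucleotide sequences (character strings or
#'   [Biostrings::DNAString]) over the alphabet A, C, G, T, N.
#' @param scoring Alignment parameters, see [screen_scoring()].
#' @return Identity in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(seq_a, seq_b, scoring = screen_scoring()) {
  a <- toupper(as.character(seq_a)); b <- toupper(as.character(seq_b))
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = screen_submat(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  identity_from_alignment(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

# identity from two equal-width gapped strings, excluding terminal gaps
identity_from_alignment <- function(p, s) {
  pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
  w <- length(pc)
  gap <- pc == "-" | sc == "-"
  lead <- 0L
  while (lead < w && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < w - lead && gap[w - trail]) trail <- trail + 1L
  cols <- seq.int(lead + 1L, w - trail)
  if (length(cols) == 0) return(0)
  matches <- sum(pc[cols] == sc[cols] & pc[cols] != "-" & pc[cols] != "N")
  matches / length(cols)
}

# identity of many queries against one subject, vectorised
identities_vs_subject <- function(queries, subject, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    queries, subject, type = "global",
    substitutionMatrix = screen_submat(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(p), function(i) identity_from_alignment(p[i], s[i]),
         numeric(1))
}

as_named_dss <- function(x, prefix) {
  x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    names(x) <- sprintf("%s%03d", prefix, seq_along(x))
  x
}

#' Greedy dereplication of reference sequences
#'
#' Length-ordered greedy centroid selection: sequences are visited from
#' longest to shortest (ties by input order); a sequence joins the first
#' existing centroid it matches at `identity >= threshold`, otherwise it is
#' retained as a new centroid. Output order is the deterministic order of
#' centroid creation.
#'
#' @param refs Sequences ([Biostrings::DNAStringSet] or character vector).
#' @param threshold Identity threshold in `[0, 1]`.
#' @param scoring Alignment parameters, see [screen_scoring()].
#' @return [Biostrings::DNAStringSet] of centroids with a
#'   `"membership"` attribute mapping every input id to its centroid id.
#' @export
dereplicate_references <- function(refs, threshold,
                                   scoring = screen_scoring()) {
  refs <- as_named_dss(refs, "ref")
  if (length(refs) == 0) stop("refs must be non-empty")
  ord <- order(-Biostrings::width(refs), seq_along(refs))
  centroid_idx <- integer(0)
  membership <- setNames(character(length(refs)), names(refs))
  for (i in ord) {
    assigned <- FALSE
    for (cix in centroid_idx) {
      idv <- pairwise_identity(refs[[i]], refs[[cix]], scoring)
      if (idv >= threshold) {
        membership[names(refs)[i]] <- names(refs)[cix]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      centroid_idx <- c(centroid_idx, i)
      membership[names(refs)[i]] <- names(refs)[i]
    }
  }
  out <- refs[centroid_idx]
  attr(out, "membership") <- membership
  out
}

#' Screen query ASVs against guild reference centroids
#'
#' Scores each query against every centroid by global-alignment identity;
#' the best reference is the argmax (ties broken by centroid input order)
#' and membership is called when the best identity meets the threshold
#' (boundary inclusive).
#'
#' @param queries Query sequences (named [Biostrings::DNAStringSet] or
#'   character vector).
#' @param centroids Non-empty reference centroid set.
#' @param threshold Membership identity threshold (default 0.89).
#' @param scoring Alignment parameters, see [screen_scoring()].
#' @return Data frame with one row per query: `query_id`, `best_ref_id`,
#'   `identity`, `member`.
#' @export
screen_queries <- function(queries, centroids, threshold = 0.89,
                           scoring = screen_scoring()) {
  centroids <- as_named_dss(centroids, "ref")
  if (length(centroids) == 0) stop("centroids must be non-empty")
  queries <- as_named_dss(queries, "q")
  if (length(queries) == 0)
    return(data.frame(query_id = character(0), best_ref_id = character(0),
                      identity = numeric(0), member = logical(0)))
  idm <- vapply(seq_along(centroids), function(j)
    identities_vs_subject(queries, centroids[[j]], scoring),
    numeric(length(queries)))
  idm <- matrix(idm, nrow = length(queries))
  best <- apply(idm, 1, which.max)   # first max -> centroid input order
  best_id <- idm[cbind(seq_along(best), best)]
  data.frame(query_id = names(queries),
             best_ref_id = names(centroids)[best],
             identity = best_id,
             member = best_id >= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
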