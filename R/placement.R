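#' Trait-labelled reference phylogeny
#'
#' Bundles a rooted reference tree with its tip alignment, binary trait
#' labels (DMSP-synthesis capability inferred from gene content of the
#' reference strains) and genus labels, and validates their consistency.
#'
#' @param tree Rooted [ape::phylo] tree with non-negative branch lengths.
#' @param alignment Character matrix of aligned sequences (tips x columns,
#'   rownames = tip labels, gaps as `"-"`), or a named character vector /
#'   [Biostrings::DNAStringSet] of equal-length aligned sequences.
#' @param traits Named character vector, one of `"producer"` /
#'   `"nonproducer"` per tip.
#' @param genus Named character vector of genus labels per tip.
#' @return Object of class `"reference_phylogeny"`.
#' @export
reference_phylogeny <- function(tree, alignment, traits, genus = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  alignment <- as_alignment_matrix(alignment)
  tips <- tree$tip.label
  if (!all(tips %in% rownames(alignment)))
    stop("every tip needs an alignment row")
  if (!all(tips %in% names(traits)))
    stop("every tip needs a trait label")
  if (!all(traits[tips] %in% c("producer", "nonproducer")))
    stop("traits must be 'producer' or 'nonproducer'")
  if (is.null(genus)) genus <- setNames(rep(NA_character_, length(tips)), tips)
  if (!all(tips %in% names(genus)))
    stop("every tip needs a genus label")
  obj <- list(tree = tree, alignment = alignment[tips, , drop = FALSE],
              traits = traits[tips], genus = genus[tips])
  class(obj) <- "reference_phylogeny"
  obj
}

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    alignment <- as.character(alignment)
    if (is.null(names(alignment))) stop("alignment sequences must be named")
    if (length(unique(nchar(alignment))) != 1)
      stop("alignment rows must have equal length")
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
  }
  m
}

## Jukes-Cantor message: (P(t) %*% C) for a 4 x L conditional matrix C.
## P has diagonal a = 1/4 + 3/4 e and off-diagonal b = 1/4 - 1/4 e with
## e = exp(-4 t / 3).
jc_message <- function(C, t) {
  e <- exp(-4 * t / 3)
  a <- 0.25 + 0.75 * e
  b <- 0.25 - 0.25 * e
  S <- rep(colSums(C), each = 4)
  (a - b) * C + b * S
}

tip_conditional <- function(chars) {
  states <- c("A", "C", "G", "T")
  L <- length(chars)
  C <- matrix(1, 4, L)
  known <- chars %in% states
  C[, known] <- 0
  C[cbind(match(chars[known], states), which(known))] <- 1
  C
}

## Down (subtree) conditionals per node and up (rest-of-tree) conditionals
## per edge, for reuse across queries.
placement_engine <- function(ref) {
  tree <- ref$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- ncol(ref$alignment)
  down <- vector("list", nnode)
  for (i in seq_len(ntip))
    down[[i]] <- tip_conditional(ref$alignment[tree$tip.label[i], ])
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; chd <- po$edge[e, 2]
    msg <- jc_message(down[[chd]], po$edge.length[e])
    down[[par]] <- if (is.null(down[[par]])) msg else down[[par]] * msg
  }
  ## up conditionals: for edge (u,v), out[[edge]] is the conditional of
  ## everything outside the subtree of v, expressed at u
  edge <- tree$edge
  elen <- tree$edge.length
  root <- ntip + 1L
  A <- vector("list", nnode)
  A[[root]] <- matrix(1, 4, L)
  out <- vector("list", nrow(edge))
  co <- rev(postorder_edges(tree))   # preorder over edges
  for (e in co) {
    u <- edge[e, 1]; v <- edge[e, 2]
    sibs <- which(edge[, 1] == u & edge[, 2] != v)
    O <- A[[u]]
    for (s2 in sibs) O <- O * jc_message(down[[edge[s2, 2]]], elen[s2])
    out[[e]] <- O
    A[[v]] <- jc_message(O, elen[e])
  }
  list(tree = tree, down = down, out = out, L = L, ntip = ntip)
}

postorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  match(paste(po$edge[, 1], po$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Place an aligned query on a reference phylogeny
#'
#' Attaches the query mid-edge on every edge of the reference tree with each
#' pendant length in `pendant_grid`, computing the attachment log-likelihood
#' under the Jukes--Cantor model by Felsenstein pruning. The per-edge
#' likelihood is the maximum over the pendant grid; like-weight ratios are
#' the per-edge likelihoods normalised across edges and act as posterior
#' probabilities for trait assignment.
#'
#' @param query Aligned query sequence (string, character vector of
#'   residues, or [Biostrings::DNAString]); must use the reference alignment
#'   columns, gaps as `"-"`. Positions outside A/C/G/T contribute no
#'   information.
#' @param ref A [reference_phylogeny()].
#' @param pendant_grid Pendant branch lengths tried at every edge.
#' @param engine Optional precomputed engine (see Details) for repeated
#'   placement against one reference.
#' @return Object of class `"placement_result"`: data frame `edges`
#'   (edge id, parent, child, loglik, lwr, trait), `best_edge`,
#'   `best_loglik`, `post_producer`, `post_nonproducer` (cumulative lwr on
#'   edges of each trait), and `query_id`.
#' @export
place_query <- function(query, ref,
                        pendant_grid = c(0.001, 0.01, 0.05, 0.1, 0.3),
                        engine = NULL) {
  qc <- query_chars(query, ncol(ref$alignment))
  if (!any(qc %in% c("A", "C", "G", "T")))
    stop("unplaceable: query has zero non-gap positions")
  if (is.null(engine)) engine <- placement_engine(ref)
  tree <- engine$tree
  Q <- tip_conditional(qc)
  n_edge <- nrow(tree$edge)
  ll <- numeric(n_edge)
  for (e in seq_len(n_edge)) {
    te <- tree$edge.length[e]
    v <- tree$edge[e, 2]
    distal <- jc_message(engine$down[[v]], te / 2)
    prox <- jc_message(engine$out[[e]], te / 2)
    base <- distal * prox
    best <- -Inf
    for (p in pendant_grid) {
      sl <- colSums(0.25 * base * jc_message(Q, p))
      cand <- sum(log(sl))
      if (cand > best) best <- cand
    }
    ll[e] <- best
  }
  lwr <- exp(ll - max(ll))
  lwr <- lwr / sum(lwr)
  tr <- edge_traits(ref)
  edges <- data.frame(edge = seq_len(n_edge),
                      parent = tree$edge[, 1], child = tree$edge[, 2],
                      loglik = ll, lwr = lwr, trait = tr,
                      stringsAsFactors = FALSE)
  res <- list(query_id = attr(query, "query_id") %||% NA_character_,
              edges = edges,
              best_edge = which.max(ll),
              best_loglik = max(ll),
              post_producer = sum(lwr[tr == "producer"], na.rm = TRUE),
              post_nonproducer = sum(lwr[tr == "nonproducer"], na.rm = TRUE))
  class(res) <- "placement_result"
  res
}

query_chars <- function(query, L) {
  if (inherits(query, "XString")) query <- as.character(query)
  qc <- if (length(query) == 1) strsplit(toupper(query), "")[[1]]
        else toupper(as.character(query))
  if (length(qc) != L)
    stop("query must be aligned to the reference columns (length ", L, ")")
  qc
}

#' Trait of every edge of a reference phylogeny
#'
#' An edge inherits the trait of the tip(s) nearest to its midpoint by path
#' length; if the nearest tips carry discordant traits the edge has no trait
#' (`NA`) and contributes to neither cumulative like-weight ratio.
#'
#' @param ref A [reference_phylogeny()].
#' @return Character vector over edges: `"producer"`, `"nonproducer"` or
#'   `NA`.
#' @export
edge_traits <- function(ref) {
  tree <- ref$tree
  ntip <- length(tree$tip.label)
  D <- ape::dist.nodes(tree)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    te <- tree$edge.length[e]
    below <- tips_below(tree, v, ntip)
    d <- numeric(ntip)
    for (tp in seq_len(ntip))
      d[tp] <- te / 2 + if (tp %in% below) D[v, tp] else D[u, tp]
    nearest <- which(d <= min(d) + 1e-12)
    tt <- unique(ref$traits[tree$tip.label[nearest]])
    if (length(tt) == 1) tt else NA_character_
  }, character(1))
}

tips_below <- function(tree, node, ntip) {
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree, ntip = ntip))
}

#' Assign producer status from a placement
#'
#' A query is called a producer (non-producer) when the cumulative
#' like-weight ratio on producer (non-producer) edges reaches
#' `posterior_threshold`; otherwise it stays unclassified. The optional
#' absolute log-likelihood gate, when enabled, additionally requires
#' `best_loglik < loglik_ceiling`; it is off by default because an absolute
#' likelihood is alignment-length dependent.
#'
#' @param p A [place_query()] result.
#' @param ref The [reference_phylogeny()] used for the placement.
#' @param posterior_threshold Cumulative like-weight ratio required.
#' @param loglik_ceiling Optional gate, `NULL` to disable.
#' @return One of `"producer"`, `"nonproducer"`, `"unclassified"`.
#' @export
assign_producer_status <- function(p, ref, posterior_threshold = 0.90,
                                   loglik_ceiling = NULL) {
  if (!is.null(loglik_ceiling) && !(p$best_loglik < loglik_ceiling))
    return("unclassified")
  if (p$post_producer >= posterior_threshold) return("producer")
  if (p$post_nonproducer >= posterior_threshold) return("nonproducer")
  "unclassified"
}

#' Grade a producer by genus-level intracellular DMSP concentration
#'
#' Producers whose genus has a measured intracellular concentration above
#' the split are high producers (HiDP), below it low producers (LoDP);
#' producers of genera absent from the table are unquantified (UnDP);
#' non-producers are NoDP; unclassified stays unclassified.
#'
#' @param status `"producer"`, `"nonproducer"` or `"unclassified"` (from
#'   [assign_producer_status()]).
#' @param asv_genus Genus of the ASV (may be `NA`).
#' @param table Data frame with columns `genus` and `dmsp_mM`.
#' @param split Concentration split in mM (default 50).
#' @param equal_side Class used when the concentration equals the split
#'   exactly (default `"HiDP"`, reported via a message).
#' @return One of `"HiDP"`, `"LoDP"`, `"UnDP"`, `"NoDP"`, `"unclassified"`.
#' @export
classify_production_level <- function(status, asv_genus, table, split = 50,
                                      equal_side = c("HiDP", "LoDP")) {
  equal_side <- match.arg(equal_side)
  if (status == "unclassified") return("unclassified")
  if (status == "nonproducer") return("NoDP")
  if (is.na(asv_genus) || !asv_genus %in% table$genus) return("UnDP")
  conc <- table$dmsp_mM[match(asv_genus, table$genus)]
  if (conc == split) {
    message("genus '", asv_genus, "' at exactly the ", split,
            " mM split: classified ", equal_side)
    return(equal_side)
  }
  if (conc > split) "HiDP" else "LoDP"
}

#' Classify a set of query ASVs end to end
#'
#' Places each aligned query, gates the trait call on the placement
#' posterior, and grades producers by genus concentration.
#'
#' @param queries Named set of aligned query sequences
#'   ([Biostrings::DNAStringSet], named character vector, or alignment
#'   matrix).
#' @param ref A [reference_phylogeny()].
#' @param genus_table Data frame with columns `genus`, `dmsp_mM`.
#' @param query_genus Optional named genus per query (defaults to the genus
#'   of the best placement edge's nearest reference tip).
#' @param config An [analysis_config()].
#' @param pendant_grid Pendant lengths, see [place_query()].
#' @return Data frame: `query_id`, `status`, `producer_class`,
#'   `post_producer`, `post_nonproducer`, `best_loglik`, `genus`. The
#'   producer classes partition the input queries.
#' @export
classify_queries <- function(queries, ref, genus_table,
                             query_genus = NULL,
                             config = analysis_config(),
                             pendant_grid = c(0.001, 0.01, 0.05, 0.1, 0.3)) {
  qmat <- as_alignment_matrix(queries)
  engine <- placement_engine(ref)
  tr <- ref$traits
  rows <- lapply(rownames(qmat), function(qid) {
    p <- place_query(qmat[qid, ], ref, pendant_grid, engine = engine)
    status <- assign_producer_status(p, ref, config$posterior_threshold,
                                     config$loglik_ceiling)
    g <- if (!is.null(query_genus) && qid %in% names(query_genus))
      query_genus[[qid]]
    else {
      best_child <- p$edges$child[p$best_edge]
      tips <- tips_below(ref$tree, best_child, length(ref$tree$tip.label))
      unname(ref$genus[ref$tree$tip.label[tips[1]]])
    }
    data.frame(query_id = qid, status = status,
               producer_class = classify_production_level(
                 status, g, genus_table, config$hidp_split_mM,
                 config$hidp_equal_side),
               post_producer = p$post_producer,
               post_nonproducer = p$post_nonproducer,
               best_loglik = p$best_loglik,
               genus = g %||% NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Align a query to the reference alignment columns
#'
#' Profile alignment against the column-consensus of the reference
#' alignment: the query is globally aligned to the consensus sequence,
#' query insertions relative to the consensus are dropped, and deleted
#' columns become gaps, yielding a query row in reference coordinates.
#'
#' @param query Unaligned query sequence (string or
#'   [Biostrings::DNAString]).
#' @param ref A [reference_phylogeny()].
#' @param scoring Alignment parameters, see [screen_scoring()].
#' @return Character string of length `ncol(ref$alignment)`.
#' @export
align_to_reference <- function(query, ref, scoring = screen_scoring()) {
  cons <- apply(ref$alignment, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0) "A" else names(which.max(table(col)))
  })
  cons_str <- paste(cons, collapse = "")
  q <- toupper(as.character(query))
  aln <- Biostrings::pairwiseAlignment(
    q, cons_str, type = "global", substitutionMatrix = screen_submat(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- character(length(cons))
  col <- 0L
  for (i in seq_along(s)) {
    if (s[i] != "-") {        # a consensus (reference) column
      col <- col + 1L
      out[col] <- if (p[i] == "-") "-" else p[i]
    }                         # else: query insertion, dropped
  }
  paste(out, collapse = "")
}

#' Write placements as jplace-compatible JSON
#'
#' @param placements List of [place_query()] results.
#' @param ref The [reference_phylogeny()] they were computed against.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_jplace <- function(placements, ref, path) {
  tree_str <- ape::write.tree(ref$tree)
  recs <- lapply(placements, function(p) {
    list(p = lapply(seq_len(nrow(p$edges)), function(i)
      list(p$edges$edge[i], p$edges$loglik[i], p$edges$lwr[i])),
      n = list(p$query_id))
  })
  obj <- list(version = 3,
              tree = tree_str,
              placements = recs,
              fields = list("edge_num", "likelihood", "like_weight_ratio"),
              metadata = list(invocation = "roseonet::write_jplace"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
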