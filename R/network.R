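#' Score a bacteria x phytoplankton (and covariate) co-occurrence network
#'
#' Scores every bacterial-by-phytoplankton and bacterial-by-covariate pair
#' with MICe, TICe and Spearman rho on per-sample relative abundances. An
#' edge is significant when `TICe > tic_min` (a relationship is present)
#' and `MICe >= mic_threshold` (the relationship is significant at the
#' calibrated level). Covariate edges are computed on the subset of samples
#' with complete covariate data; taxon-taxon edges use all shared samples.
#'
#' @param bact Count matrix (samples x bacterial ASVs), already restricted
#'   to the features of interest (e.g. top-k guild plus top-k non-guild).
#' @param phyto Count matrix (samples x phytoplankton ASVs), sample-aligned
#'   with `bact`.
#' @param guilds Named vector over `colnames(bact)` with values `"MRG"` /
#'   `"nonMRG"` (or logical, `TRUE` = guild member).
#' @param classes Named vector over `colnames(phyto)` with producer classes
#'   (`"HiDP"`, `"LoDP"`, `"UnDP"`, `"NoDP"`).
#' @param covariates Optional numeric data frame / matrix of per-sample
#'   environmental covariates (rownames = sample ids).
#' @param config An [analysis_config()].
#' @return Data frame of edge records: `node_a`, `node_b`, `mic_e`,
#'   `tic_e`, `rho`, `n`, `significant`, `guild_a`, `class_b`.
#' @export
build_network <- function(bact, phyto, guilds, classes, covariates = NULL,
                          config = analysis_config()) {
  bact <- as.matrix(bact); phyto <- as.matrix(phyto)
  if (!identical(rownames(bact), rownames(phyto))) {
    bad <- c(setdiff(rownames(bact), rownames(phyto)),
             setdiff(rownames(phyto), rownames(bact)))
    stop("sample misalignment between tables: ",
         paste(unique(bad), collapse = ", "))
  }
  if (is.logical(guilds)) guilds <- ifelse(guilds, "MRG", "nonMRG")
  if (!all(colnames(bact) %in% names(guilds)))
    stop("every bacterial feature needs a guild annotation")
  if (!all(colnames(phyto) %in% names(classes)))
    stop("every phytoplankton feature needs a producer class")
  n_all <- nrow(bact)
  if (n_all < config$min_pairwise_n)
    stop("need at least ", config$min_pairwise_n, " shared samples")
  rb <- relative_abundance(bact)
  rp <- relative_abundance(phyto)

  score_pair <- function(x, y) {
    const <- length(unique(x)) < 2 || length(unique(y)) < 2
    if (const)
      return(list(mic = 0, tic = 0, rho = NA_real_))
    st <- mine_stat_cpp(x, y, config$mine_alpha, config$max_clumps_factor)
    list(mic = st$mic, tic = st$tic,
         rho = suppressWarnings(spearman_rho(x, y)))
  }

  rows <- vector("list", ncol(rb) * (ncol(rp) +
    if (is.null(covariates)) 0 else ncol(covariates)))
  k <- 0L
  for (a in colnames(rb)) {
    for (b in colnames(rp)) {
      s <- score_pair(rb[, a], rp[, b])
      k <- k + 1L
      rows[[k]] <- data.frame(
        node_a = a, node_b = b, mic_e = s$mic, tic_e = s$tic, rho = s$rho,
        n = n_all,
        significant = s$tic > config$tic_min & s$mic >= config$mic_threshold,
        guild_a = unname(guilds[a]), class_b = unname(classes[b]),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!all(rownames(bact) %in% rownames(covariates)))
      stop("sample misalignment with covariates: ",
           paste(setdiff(rownames(bact), rownames(covariates)),
                 collapse = ", "))
    covariates <- covariates[rownames(bact), , drop = FALSE]
    cc <- stats::complete.cases(covariates)
    if (sum(cc) >= config$min_pairwise_n) {
      for (a in colnames(rb)) {
        for (b in colnames(covariates)) {
          s <- score_pair(rb[cc, a], covariates[cc, b])
          k <- k + 1L
          rows[[k]] <- data.frame(
            node_a = a, node_b = b, mic_e = s$mic, tic_e = s$tic,
            rho = s$rho, n = sum(cc),
            significant = s$tic > config$tic_min &
              s$mic >= config$mic_threshold,
            guild_a = unname(guilds[a]), class_b = "covariate",
            stringsAsFactors = FALSE)
        }
      }
    } else {
      warning("fewer than ", config$min_pairwise_n,
              " covariate-complete samples: covariate edges skipped")
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Guild-level comparison of mean correlation strength
#'
#' Averages Spearman rho over significant positive edges within every
#' guild-by-producer-class cell and compares the cells with the
#' homoscedasticity-gated rule of [compare_groups()] (Levene-gated
#' ANOVA/Tukey--Kramer or Kruskal--Wallis).
#'
#' @param edges Edge records from [build_network()].
#' @param alpha Significance level for the comparison.
#' @param min_cell Minimum number of edges per cell to enter the omnibus
#'   comparison (cells below it are summarised but excluded, and reported).
#' @return List of class `"guild_summary"`: `cells` (data frame: `guild`,
#'   `class`, `mean_rho`, `sd_rho`, `n_edges`), `comparison` (a
#'   [compare_groups()] result or `NULL`), `top_cell`, `evaluable`,
#'   `excluded_cells`.
#' @export
guild_mean_comparison <- function(edges, alpha = 0.05, min_cell = 3) {
  use <- edges$significant & !is.na(edges$rho) & edges$rho > 0 &
    edges$class_b != "covariate"
  e <- edges[use, , drop = FALSE]
  if (nrow(e) == 0)
    return(structure(list(cells = NULL, comparison = NULL,
                          top_cell = NA_character_, evaluable = FALSE,
                          excluded_cells = character(0)),
                     class = "guild_summary"))
  cell <- paste(e$guild_a, e$class_b, sep = ":")
  agg <- do.call(rbind, lapply(split(e$rho, cell), function(v)
    data.frame(mean_rho = mean(v), sd_rho = sd(v), n_edges = length(v))))
  parts <- strsplit(rownames(agg), ":", fixed = TRUE)
  cells <- data.frame(guild = vapply(parts, `[`, "", 1),
                      class = vapply(parts, `[`, "", 2),
                      agg, stringsAsFactors = FALSE, row.names = NULL)
  cells <- cells[order(-cells$mean_rho), ]
  ## cells entering the omnibus comparison need >= 3 edges (the test's own
  ## per-group minimum), independent of the reporting threshold
  ok_cells <- rownames(agg)[agg$n_edges >= max(min_cell, 3)]
  excluded <- setdiff(rownames(agg), ok_cells)
  comparison <- NULL
  evaluable <- length(ok_cells) >= 2
  if (evaluable) {
    sel <- cell %in% ok_cells
    comparison <- compare_groups(e$rho[sel], cell[sel], alpha = alpha)
  }
  structure(list(cells = cells, comparison = comparison,
                 top_cell = paste(cells$guild[1], cells$class[1], sep = ":"),
                 evaluable = evaluable, excluded_cells = excluded),
            class = "guild_summary")
}

#' Strong-edge subnetwork
#'
#' Subsets the significant edges with Spearman rho strictly above
#' `rho_min` (the strong-correlation view of the network).
#'
#' @param edges Edge records from [build_network()].
#' @param rho_min Strict lower bound on rho (default 0.6).
#' @return Edge-record data frame (possibly empty).
#' @export
strong_subnetwork <- function(edges, rho_min = 0.6) {
  edges[edges$significant & !is.na(edges$rho) & edges$rho > rho_min, ,
        drop = FALSE]
}

#' Convert edge records to an igraph graph
#'
#' Node attributes carry the guild / producer-class annotation and, when
#' `abundance` is supplied, the mean relative abundance; edges carry `rho`,
#' `mic_e` and `tic_e`.
#'
#' @param edges Edge records from [build_network()] /
#'   [strong_subnetwork()].
#' @param abundance Optional named vector of mean relative abundance per
#'   node.
#' @return An [igraph::graph] object.
#' @export
edges_to_igraph <- function(edges, abundance = NULL) {
  nodes <- data.frame(
    name = c(edges$node_a, edges$node_b),
    role = c(edges$guild_a, edges$class_b), stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  if (!is.null(abundance))
    nodes$abundance <- ifelse(nodes$name %in% names(abundance),
                              abundance[nodes$name], NA_real_)
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b", "rho", "mic_e", "tic_e")],
    directed = FALSE, vertices = nodes)
  g
}

#' Write an edge list as GraphML
#'
#' @param edges Edge records.
#' @param path Output file.
#' @param abundance Optional node abundance attribute, see
#'   [edges_to_igraph()].
#' @return `path`, invisibly. An empty edge set writes an empty graph.
#' @export
write_graphml <- function(edges, path, abundance = NULL) {
  g <- if (nrow(edges) == 0) igraph::make_empty_graph(directed = FALSE)
       else edges_to_igraph(edges, abundance)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
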