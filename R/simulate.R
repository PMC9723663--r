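#' Generate synthetic multi-site monthly community time series
#'
#' Emulates the statistical structure of monthly oceanographic time-series
#' amplicon data: per-ASV log baselines drawn from a lognormal rank-abundance
#' curve, site-specific seasonal sine forcing with ASV-specific phase, a
#' poleward abundance gradient for guild members, log-linear couplings from
#' phytoplankton latent abundances into bacterial abundances, and
#' negative-binomial counts multinomially closed to a fixed library size
#' (compositional, as relative-abundance analyses assume).
#'
#' The expected log abundance of ASV `i` at site `s`, month `t` is
#' `baseline_i + amplitude_s * sin(2*pi*(t - phase_i)/12) + sum_j c_ij z_j(t)`
#' where `z_j` is the centred latent log abundance of producer `j` (the
#' coupling term applies to bacterial ASVs only).
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `"community_simulation"` with elements
#'   `bact` and `phyto` (integer count matrices, samples x ASVs),
#'   `metadata` (data frame: sample_id, site, year, month, depth and
#'   physicochemical covariates co-varying with season), and `truth`
#'   (ground truth: `guild` logical per bacterial ASV, `producer_class`
#'   per phytoplankton ASV, `planted_edges` data frame, `seasonal_sites`).
#' @export
generate_time_series <- function(cfg = simulation_config()) {
  validate_simulation_config(cfg)
  if (cfg$months < 24 && any(cfg$seasonal_amplitude > 0))
    warning("fewer than 24 monthly samples with seasonality requested: ",
            "seasonality tests will be underpowered")

  nb <- cfg$n_bact_asvs; np <- cfg$n_phyto_asvs
  bact_ids <- sprintf("b%03d", seq_len(nb))
  phyto_ids <- sprintf("p%03d", seq_len(np))
  sites <- sprintf("site%02d", seq_len(cfg$n_sites))

  ## stage 1: community structure (baselines, phases, truth labels)
  set.seed(cfg$seed + 1L)
  base_b <- rnorm(nb, 0, cfg$baseline_sd)
  base_p <- rnorm(np, 0, cfg$baseline_sd)
  phase_b <- runif(nb, 0, 12)
  phase_p <- runif(np, 0, 12)
  n_guild <- round(cfg$guild_fraction * nb)
  guild <- setNames(seq_len(nb) <= n_guild, bact_ids)
  pclass <- setNames(
    producer_class_layout(np, cfg$trait_fraction, cfg$hidp_fraction),
    phyto_ids)

  grad <- if (cfg$n_sites > 1)
    cfg$lat_gradient * (seq_len(cfg$n_sites) - 1) / (cfg$n_sites - 1)
  else rep(0, 1)

  ## stage 2: latent dynamics and counts
  set.seed(cfg$seed + 2L)
  months_seq <- seq_len(cfg$months)
  month_of <- ((months_seq - 1) %% 12) + 1
  year_of <- 2015L + (months_seq - 1) %/% 12

  samp_meta <- list(); bact_rows <- list(); phyto_rows <- list()
  size_nb <- 1 / cfg$dispersion
  for (s in seq_len(cfg$n_sites)) {
    amp <- cfg$seasonal_amplitude[s]
    keep <- if (s %in% cfg$quarterly_sites) which((months_seq - 1) %% 3 == 0)
            else months_seq
    for (t in keep) {
      season_term_p <- amp * sin(2 * pi * (t - phase_p) / 12)
      z <- season_term_p + rnorm(np, 0, cfg$latent_sd)   # centred latent
      eta_p <- base_p + z
      season_term_b <- amp * sin(2 * pi * (t - phase_b) / 12)
      eta_b <- base_b + season_term_b + as.numeric(cfg$coupling_matrix %*% z) +
        rnorm(nb, 0, cfg$latent_sd)
      eta_b[guild] <- eta_b[guild] + grad[s]

      draw <- function(eta) {
        mu <- exp(eta - max(eta))            # relative scale
        raw <- rnbinom(length(eta), mu = mu * 1000, size = size_nb)
        if (sum(raw) == 0) raw <- mu
        as.integer(rmultinom(1, cfg$library_size, prob = raw))
      }
      bact_rows[[length(bact_rows) + 1L]] <- draw(eta_b)
      phyto_rows[[length(phyto_rows) + 1L]] <- draw(eta_p)
      samp_meta[[length(samp_meta) + 1L]] <-
        data.frame(site = sites[s], year = year_of[t], month = month_of[t],
                   t_index = t, amp = amp, stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, samp_meta)
  meta$sample_id <- sprintf("%s_%04d_%02d", meta$site, meta$year, meta$month)

  bact <- do.call(rbind, bact_rows)
  phyto <- do.call(rbind, phyto_rows)
  dimnames(bact) <- list(meta$sample_id, bact_ids)
  dimnames(phyto) <- list(meta$sample_id, phyto_ids)

  ## stage 3: physicochemical covariates co-varying with season
  set.seed(cfg$seed + 3L)
  site_idx <- match(meta$site, sites)
  temp_base <- seq(28, 13, length.out = cfg$n_sites)[site_idx]
  seas <- sin(2 * pi * (meta$t_index - 1) / 12)
  meta$depth <- 0
  meta$temperature <- temp_base + 3 * seas + rnorm(nrow(meta), 0, 0.5)
  meta$chl_a <- exp(-1 + 0.6 * meta$amp * seas + rnorm(nrow(meta), 0, 0.3))
  meta$salinity <- 35.2 + rnorm(nrow(meta), 0, 0.15)
  meta$nitrate_nitrite <- pmax(0, 0.5 - 0.2 * seas + rnorm(nrow(meta), 0, 0.15))
  meta$phosphate <- pmax(0, 0.2 + rnorm(nrow(meta), 0, 0.05))
  meta$ammonia <- pmax(0, 0.1 + rnorm(nrow(meta), 0, 0.04))
  meta$silicate <- pmax(0, 1 + 0.3 * seas + rnorm(nrow(meta), 0, 0.2))
  meta$oxygen <- 220 - 2 * (meta$temperature - mean(meta$temperature)) +
    rnorm(nrow(meta), 0, 5)
  meta$amp <- NULL
  meta <- meta[, c("sample_id", "site", "year", "month", "t_index", "depth",
                   "temperature", "salinity", "chl_a", "nitrate_nitrite",
                   "phosphate", "ammonia", "silicate", "oxygen")]
  rownames(meta) <- meta$sample_id

  planted <- which(cfg$coupling_matrix != 0, arr.ind = TRUE)
  planted_edges <- data.frame(
    bact = bact_ids[planted[, 1]], phyto = phyto_ids[planted[, 2]],
    coupling = cfg$coupling_matrix[planted], stringsAsFactors = FALSE)

  out <- list(bact = bact, phyto = phyto, metadata = meta,
              truth = list(guild = guild, producer_class = pclass,
                           planted_edges = planted_edges,
                           seasonal_sites = sites[cfg$seasonal_amplitude > 0]),
              config = cfg)
  class(out) <- "community_simulation"
  out
}

#' Generate a synthetic reference set with trait-labelled phylogeny
#'
#' Simulates a rooted reference tree, evolves ungapped reference sequences
#' along it under Jukes--Cantor substitutions, labels traits clade-wise on
#' the two root clades (one producer clade, one non-producer clade), and
#' emits query sequences as copies of reference sequences carrying an exact
#' number of substitutions so that each query's identity to its source
#' reference is known to within +/- 0.5 percentage points.
#'
#' @param n_refs Number of reference sequences / tree tips (>= 4).
#' @param divergence_levels Per-query divergence in `[0, 0.75]`; queries are
#'   emitted by cycling divergence levels over source references.
#' @param tree_depth Root-to-tip depth of the reference tree in expected
#'   substitutions per site.
#' @param seed Integer seed.
#' @param seq_length Alignment length (>= 200 recommended).
#' @param queries_per_level Number of queries per divergence level.
#' @return List with `references` and `queries`
#'   ([Biostrings::DNAStringSet]), `phylogeny` (a [reference_phylogeny()]),
#'   `query_map` (data frame: query_id, source_ref, divergence,
#'   realized_identity, true_trait, genus) and `genus_table` (synthetic
#'   genus-to-DMSP-concentration table covering high and low producer
#'   genera; unquantified genera are deliberately absent).
#' @export
generate_reference_set <- function(n_refs = 8,
                                   divergence_levels = c(0.03, 0.09, 0.13),
                                   tree_depth = 0.4, seed = 1,
                                   seq_length = 400,
                                   queries_per_level = 2) {
  if (n_refs < 4) stop("n_refs must be >= 4")
  bad <- divergence_levels[abs(round(divergence_levels * seq_length) /
                                 seq_length - divergence_levels) > 0.005]
  if (length(bad) > 0)
    stop("requested divergence not achievable at length ", seq_length, ": ",
         paste(signif(bad, 3), collapse = ", "))
  if (any(divergence_levels < 0 | divergence_levels > 0.75))
    stop("divergence levels must be in [0, 0.75]")
  set.seed(seed)

  tree <- ape::rtree(n_refs, rooted = TRUE,
                     tip.label = sprintf("ref%02d", seq_len(n_refs)))
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length * tree_depth / max(depths[seq_len(n_refs)])

  bases <- c("A", "C", "G", "T")
  root_seq <- sample(bases, seq_length, replace = TRUE)
  ## evolve along edges in preorder; JC: P(observe different base) on an edge
  ## of length b is 3/4 (1 - exp(-4 b / 3))
  n_node <- n_refs + tree$Nnode
  seqs <- vector("list", n_node)
  root <- n_refs + 1L
  seqs[[root]] <- root_seq
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(eo$edge))) {
    par <- eo$edge[e, 1]; chd <- eo$edge[e, 2]
    b <- eo$edge.length[e]
    p_sub <- 0.75 * (1 - exp(-4 * b / 3))
    s <- seqs[[par]]
    hit <- which(runif(seq_length) < p_sub)
    if (length(hit) > 0)
      s[hit] <- vapply(s[hit], function(cur)
        sample(setdiff(bases, cur), 1), character(1))
    seqs[[chd]] <- s
  }
  aln <- do.call(rbind, seqs[seq_len(n_refs)])
  rownames(aln) <- tree$tip.label

  ## clade-wise traits from the two root clades
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  clade1 <- if (kids[1] <= n_refs) tree$tip.label[kids[1]] else
    ape::extract.clade(tree, kids[1])$tip.label
  traits <- setNames(ifelse(tree$tip.label %in% clade1,
                            "producer", "nonproducer"), tree$tip.label)

  ## genera: producer tips cycle over high/low/unquantified genera
  hi_genera <- c("Micromonas", "Synthamoeba_hi")    # > 50 mM in the table
  lo_genera <- c("Synthella_lo")                    # < 50 mM in the table
  un_genera <- c("Synthomonas_un")                  # absent from the table
  non_genera <- c("Synthococcus_no", "Synthiella_no")
  prod_tips <- names(traits)[traits == "producer"]
  non_tips <- names(traits)[traits == "nonproducer"]
  genus <- setNames(character(n_refs), tree$tip.label)
  genus[prod_tips] <- rep_len(c(hi_genera, lo_genera, un_genera),
                              length(prod_tips))
  genus[non_tips] <- rep_len(non_genera, length(non_tips))
  genus_table <- data.frame(
    genus = c("Micromonas", "Synthamoeba_hi", "Synthella_lo"),
    dmsp_mM = c(161.9, 80, 10), stringsAsFactors = FALSE)

  phylo <- reference_phylogeny(tree, aln, traits, genus)

  ## queries: exact substitution counts on a pendant branch
  n_q <- length(divergence_levels) * queries_per_level
  q_seqs <- character(n_q); q_map <- vector("list", n_q)
  src_cycle <- rep_len(seq_len(n_refs), n_q)
  lvl <- rep(divergence_levels, each = queries_per_level)
  for (i in seq_len(n_q)) {
    src <- src_cycle[i]
    nsub <- round(lvl[i] * seq_length)
    s <- aln[src, ]
    if (nsub > 0) {
      pos <- sample.int(seq_length, nsub)
      s[pos] <- vapply(s[pos], function(cur)
        sample(setdiff(bases, cur), 1), character(1))
    }
    q_seqs[i] <- paste(s, collapse = "")
    q_map[[i]] <- data.frame(
      query_id = sprintf("q%03d", i), source_ref = tree$tip.label[src],
      divergence = lvl[i], realized_identity = 1 - nsub / seq_length,
      true_trait = unname(traits[tree$tip.label[src]]),
      genus = unname(genus[tree$tip.label[src]]), stringsAsFactors = FALSE)
  }
  query_map <- do.call(rbind, q_map)

  refs <- Biostrings::DNAStringSet(apply(aln, 1, paste, collapse = ""))
  queries <- Biostrings::DNAStringSet(setNames(q_seqs, query_map$query_id))
  list(references = refs, queries = queries, phylogeny = phylo,
       query_map = query_map, genus_table = genus_table)
}
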