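#' Analysis configuration
#'
#' Collects every numeric threshold used across the pipeline in one place so
#' that no stage hard-codes a constant. Defaults follow the published guild
#' analysis this package implements: 16S guild membership at 89% identity,
#' placement posterior of 0.90, the 50 mM intracellular DMSP split between
#' high and low producers, MICe >= 0.178 with TICe > 0 for network inclusion,
#' Spearman rho > 0.6 for the strong subnetwork, alpha = 0.05 with Bonferroni
#' correction, austral season blocks Mar--Aug / Sep--Feb, and top-50 feature
#' subsets.
#'
#' @param identity_threshold Guild membership identity threshold (inclusive).
#' @param posterior_threshold Cumulative like-weight ratio needed to assign a
#'   placement trait.
#' @param loglik_ceiling Optional absolute log-likelihood gate for placements;
#'   `NULL` (default) disables it. When set, a query is only classified if its
#'   best attachment log-likelihood is below the ceiling.
#' @param hidp_split_mM Intracellular DMSP concentration (mM) separating high
#'   from low producers.
#' @param hidp_equal_side Class assigned when a genus concentration equals the
#'   split exactly; `"HiDP"` (default) or `"LoDP"`.
#' @param mic_threshold MICe network-inclusion threshold.
#' @param tic_min Edges require TICe strictly greater than this value.
#' @param rho_strong Spearman rho threshold (strict) for the strong subnetwork.
#' @param alpha Significance level before Bonferroni correction.
#' @param season_aw,season_ss Integer calendar months of the Autumn--Winter and
#'   Spring--Summer blocks.
#' @param top_k Number of most-abundant features retained per group.
#' @param mine_alpha Grid-bound exponent for MICe/TICe, B(n) = n^mine_alpha.
#' @param max_clumps_factor Clump cap factor for the MICe dynamic programme.
#' @param min_pairwise_n Minimum pairwise-complete sample count per edge.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(identity_threshold = 0.89,
                            posterior_threshold = 0.90,
                            loglik_ceiling = NULL,
                            hidp_split_mM = 50,
                            hidp_equal_side = c("HiDP", "LoDP"),
                            mic_threshold = 0.178,
                            tic_min = 0,
                            rho_strong = 0.6,
                            alpha = 0.05,
                            season_aw = 3:8,
                            season_ss = c(9:12, 1:2),
                            top_k = 50,
                            mine_alpha = 0.6,
                            max_clumps_factor = 5,
                            min_pairwise_n = 30) {
  hidp_equal_side <- match.arg(hidp_equal_side)
  cfg <- list(identity_threshold = identity_threshold,
              posterior_threshold = posterior_threshold,
              loglik_ceiling = loglik_ceiling,
              hidp_split_mM = hidp_split_mM,
              hidp_equal_side = hidp_equal_side,
              mic_threshold = mic_threshold,
              tic_min = tic_min,
              rho_strong = rho_strong,
              alpha = alpha,
              season_aw = as.integer(season_aw),
              season_ss = as.integer(season_ss),
              top_k = as.integer(top_k),
              mine_alpha = mine_alpha,
              max_clumps_factor = max_clumps_factor,
              min_pairwise_n = as.integer(min_pairwise_n))
  validate_analysis_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_analysis_config <- function(cfg) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop(sprintf("config field '%s' must be a single value in [0, 1]", nm),
           call. = FALSE)
  }
  chk01(cfg$identity_threshold, "identity_threshold")
  chk01(cfg$posterior_threshold, "posterior_threshold")
  chk01(cfg$mic_threshold, "mic_threshold")
  chk01(cfg$alpha, "alpha")
  if (!is.null(cfg$loglik_ceiling) &&
      (!is.numeric(cfg$loglik_ceiling) || length(cfg$loglik_ceiling) != 1))
    stop("config field 'loglik_ceiling' must be NULL or a single number",
         call. = FALSE)
  if (cfg$hidp_split_mM <= 0)
    stop("config field 'hidp_split_mM' must be positive", call. = FALSE)
  if (cfg$rho_strong < -1 || cfg$rho_strong > 1)
    stop("config field 'rho_strong' must be in [-1, 1]", call. = FALSE)
  if (cfg$top_k < 1) stop("config field 'top_k' must be >= 1", call. = FALSE)
  if (length(intersect(cfg$season_aw, cfg$season_ss)) > 0 ||
      !setequal(c(cfg$season_aw, cfg$season_ss), 1:12))
    stop("config fields 'season_aw'/'season_ss' must partition months 1..12",
         call. = FALSE)
  invisible(cfg)
}

#' Simulation configuration for synthetic community time series
#'
#' Defines the multi-site monthly sampling design the simulator emulates:
#' site-specific seasonal amplitude on the log scale, a latitudinal abundance
#' gradient for guild members, log-linear couplings from phytoplankton latent
#' abundances into bacterial abundances, and negative-binomial counts closed
#' to a fixed library size.
#'
#' @param n_sites Number of sites.
#' @param months Number of consecutive monthly samples per site.
#' @param n_bact_asvs,n_phyto_asvs Number of bacterial / phytoplankton ASVs.
#' @param seasonal_amplitude Non-negative per-site sine amplitude on the log
#'   abundance scale (recycled to `n_sites`). The default spans no seasonality
#'   at the most tropical site to strong seasonality at the most temperate.
#' @param coupling_matrix `n_bact_asvs x n_phyto_asvs` matrix of log-linear
#'   coupling coefficients (default all zero).
#' @param library_size Reads per sample after closure.
#' @param dispersion Negative-binomial overdispersion (counts use
#'   `size = 1/dispersion`).
#' @param trait_fraction Fraction of phytoplankton ASVs that are DMSP
#'   producers.
#' @param hidp_fraction Fraction of producers assigned to high-DMSP genera.
#' @param guild_fraction Fraction of bacterial ASVs that belong to the target
#'   guild.
#' @param baseline_sd Standard deviation of per-ASV log baseline abundances.
#' @param latent_sd Standard deviation of the month-to-month latent noise.
#' @param lat_gradient Log-abundance increase of guild members from the first
#'   (most tropical) to the last (most temperate) site.
#' @param quarterly_sites Optional integer site indices thinned to quarterly
#'   sampling (every third month).
#' @param seed Integer seed; identical configurations reproduce identical
#'   output.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_sites = 3,
                              months = 36,
                              n_bact_asvs = 60,
                              n_phyto_asvs = 40,
                              seasonal_amplitude = NULL,
                              coupling_matrix = NULL,
                              library_size = 10000,
                              dispersion = 0.5,
                              trait_fraction = 0.4,
                              hidp_fraction = 0.3,
                              guild_fraction = 0.4,
                              baseline_sd = 1.0,
                              latent_sd = 1.0,
                              lat_gradient = 1.0,
                              quarterly_sites = integer(0),
                              seed = 1) {
  if (is.null(seasonal_amplitude))
    seasonal_amplitude <- if (n_sites == 1) 1.0 else
      seq(0, 1.5, length.out = n_sites)
  seasonal_amplitude <- rep_len(seasonal_amplitude, n_sites)
  if (is.null(coupling_matrix))
    coupling_matrix <- matrix(0, n_bact_asvs, n_phyto_asvs)
  cfg <- list(n_sites = as.integer(n_sites), months = as.integer(months),
              n_bact_asvs = as.integer(n_bact_asvs),
              n_phyto_asvs = as.integer(n_phyto_asvs),
              seasonal_amplitude = seasonal_amplitude,
              coupling_matrix = coupling_matrix,
              library_size = as.integer(library_size),
              dispersion = dispersion,
              trait_fraction = trait_fraction,
              hidp_fraction = hidp_fraction,
              guild_fraction = guild_fraction,
              baseline_sd = baseline_sd, latent_sd = latent_sd,
              lat_gradient = lat_gradient,
              quarterly_sites = as.integer(quarterly_sites),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$library_size <= 0)
    stop("library_size must be positive", call. = FALSE)
  if (any(cfg$seasonal_amplitude < 0))
    stop("seasonal_amplitude must be non-negative", call. = FALSE)
  for (f in c("trait_fraction", "hidp_fraction", "guild_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("%s must be in [0, 1]", f), call. = FALSE)
  }
  if (cfg$dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (!all(dim(cfg$coupling_matrix) == c(cfg$n_bact_asvs, cfg$n_phyto_asvs)))
    stop("coupling_matrix must be n_bact_asvs x n_phyto_asvs", call. = FALSE)
  if (cfg$n_sites < 1 || cfg$months < 1)
    stop("n_sites and months must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Deterministic producer-class layout
#'
#' Assigns producer classes to phytoplankton ASV indices in a fixed order:
#' the first `ceiling(trait_fraction * n)` ASVs are producers, of which the
#' first `ceiling(hidp_fraction * n_producers)` are HiDP; remaining producers
#' are split (first half LoDP, rest UnDP); non-producers are NoDP. The layout
#' being index-deterministic lets callers build coupling matrices that target
#' specific guild-by-class cells before generating any data.
#'
#' @param n_phyto Number of phytoplankton ASVs.
#' @param trait_fraction Fraction of ASVs that are producers.
#' @param hidp_fraction Fraction of producers that are HiDP.
#' @return Character vector of length `n_phyto` with values
#'   `"HiDP"`, `"LoDP"`, `"UnDP"`, `"NoDP"`.
#' @export
producer_class_layout <- function(n_phyto, trait_fraction, hidp_fraction) {
  n_prod <- ceiling(trait_fraction * n_phyto)
  n_hi <- ceiling(hidp_fraction * n_prod)
  n_rest <- n_prod - n_hi
  n_lo <- ceiling(n_rest / 2)
  n_un <- n_rest - n_lo
  c(rep("HiDP", n_hi), rep("LoDP", n_lo), rep("UnDP", n_un),
    rep("NoDP", n_phyto - n_prod))
}

#' Sparse guild-by-class coupling matrix
#'
#' Builds a coupling matrix in which every bacterial ASV is coupled to a
#' few randomly chosen phytoplankton partners per producer class, with a
#' stronger coefficient for the guild-to-HiDP cell. This mirrors the
#' ecological picture of bacteria with a handful of phytoplankton partners
#' rather than diffuse coupling to the whole community, and keeps per-edge
#' association strength interpretable.
#'
#' @param guild Logical vector over bacterial ASVs (`TRUE` = guild member).
#' @param classes Producer class per phytoplankton ASV (e.g. from
#'   [producer_class_layout()]).
#' @param strength_guild_hidp Coupling coefficient for guild-to-HiDP pairs.
#' @param strength_other Coefficient for all other coupled pairs.
#' @param partners_per_class Partners drawn per bacterial ASV and class.
#' @param seed Integer seed for the partner draw.
#' @return Coupling matrix (`length(guild)` x `length(classes)`).
#' @export
guild_class_coupling <- function(guild, classes,
                                 strength_guild_hidp = 0.8,
                                 strength_other = 0.3,
                                 partners_per_class = 3, seed = 1) {
  set.seed(seed)
  cm <- matrix(0, length(guild), length(classes))
  for (i in seq_along(guild)) {
    for (cl in unique(classes)) {
      cols <- which(classes == cl)
      pick <- if (length(cols) <= partners_per_class) cols
              else sample(cols, partners_per_class)
      cm[i, pick] <- if (guild[i] && cl == "HiDP") strength_guild_hidp
                     else strength_other
    }
  }
  cm
}
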