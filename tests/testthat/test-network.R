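small_net_sim <- function(seed, cm = NULL, nb = 20, np = 12, ...) {
  cfg <- simulation_config(n_bact_asvs = nb, n_phyto_asvs = np,
                           seasonal_amplitude = 0, seed = seed, ...)
  if (!is.null(cm)) cfg$coupling_matrix <- cm
  generate_time_series(cfg)
}

test_that("edge records carry guild and class annotation, no self-edges", {
  sim <- small_net_sim(51, months = 36, n_sites = 1)
  edges <- build_network(sim$bact, sim$phyto, sim$truth$guild,
                         sim$truth$producer_class)
  expect_equal(nrow(edges), 20 * 12)
  expect_true(all(edges$node_a %in% colnames(sim$bact)))
  expect_true(all(edges$node_b %in% colnames(sim$phyto)))
  expect_true(all(edges$guild_a %in% c("MRG", "nonMRG")))
  expect_true(all(edges$class_b %in% c("HiDP", "LoDP", "UnDP", "NoDP")))
  expect_true(all(edges$n == nrow(sim$bact)))
  # significance decisions follow the stated rule exactly
  cfgA <- analysis_config()
  expect_identical(edges$significant,
                   edges$tic_e > cfgA$tic_min &
                     edges$mic_e >= cfgA$mic_threshold)
})

test_that("sample misalignment errors name the offending samples", {
  sim <- small_net_sim(52, months = 36, n_sites = 1)
  ph <- sim$phyto
  rownames(ph)[1] <- "rogue_sample"
  expect_error(build_network(sim$bact, ph, sim$truth$guild,
                             sim$truth$producer_class),
               "rogue_sample")
})

test_that("covariate edges use the complete-case subset only", {
  sim <- small_net_sim(53, months = 40, n_sites = 1)
  cov <- sim$metadata[, c("temperature", "chl_a")]
  cov$temperature[1:5] <- NA
  edges <- build_network(sim$bact, sim$phyto, sim$truth$guild,
                         sim$truth$producer_class, covariates = cov)
  ce <- edges[edges$class_b == "covariate", ]
  te <- edges[edges$class_b != "covariate", ]
  expect_true(all(ce$n == 35))
  expect_true(all(te$n == 40))
  expect_setequal(unique(ce$node_b), c("temperature", "chl_a"))
})

test_that("edge significance is invariant to node input order", {
  sim <- small_net_sim(54, months = 36, n_sites = 1)
  e1 <- build_network(sim$bact, sim$phyto, sim$truth$guild,
                      sim$truth$producer_class)
  perm_b <- sample(colnames(sim$bact))
  perm_p <- sample(colnames(sim$phyto))
  e2 <- build_network(sim$bact[, perm_b], sim$phyto[, perm_p],
                      sim$truth$guild, sim$truth$producer_class)
  key1 <- paste(e1$node_a, e1$node_b)
  key2 <- paste(e2$node_a, e2$node_b)
  e2 <- e2[match(key1, key2), ]
  expect_equal(e1$mic_e, e2$mic_e, tolerance = 1e-12)
  expect_identical(e1$significant, e2$significant)
})

test_that("with no coupling and no seasonality the network stays empty", {
  ## at the sample size for which the inclusion threshold is calibrated
  fp <- numeric(5)
  for (s in 1:5) {
    sim <- generate_time_series(simulation_config(
      n_sites = 7, months = 108, n_bact_asvs = 15, n_phyto_asvs = 10,
      seasonal_amplitude = 0, seed = 600 + s))
    edges <- build_network(sim$bact, sim$phyto, sim$truth$guild,
                           sim$truth$producer_class)
    fp[s] <- mean(edges$significant)
  }
  expect_lte(mean(fp), 0.01)
})

test_that("strong subnetwork respects the strict rho bound", {
  sim <- small_net_sim(55, months = 36, n_sites = 1)
  edges <- build_network(sim$bact, sim$phyto, sim$truth$guild,
                         sim$truth$producer_class)
  expect_equal(nrow(strong_subnetwork(edges, rho_min = 1.0)), 0)
  all_sig <- strong_subnetwork(edges, rho_min = -1.0)
  expect_equal(nrow(all_sig), sum(edges$significant & !is.na(edges$rho)))
  # planted strong couplings come back as exactly those node pairs; the
  # instance uses low overdispersion so the planted latent correlation
  # survives count noise as rho > 0.6
  cm <- matrix(0, 20, 12)
  cm[1, 1] <- 2.5; cm[5, 6] <- 2.5; cm[9, 11] <- 2.5
  hits <- 0
  for (s in 1:10) {
    sim2 <- small_net_sim(700 + s, cm = cm, months = 36, n_sites = 3,
                          dispersion = 0.1)
    e2 <- build_network(sim2$bact, sim2$phyto, sim2$truth$guild,
                        sim2$truth$producer_class)
    st <- strong_subnetwork(e2, 0.6)
    got <- sort(paste(st$node_a, st$node_b))
    if (identical(got, sort(c("b001 p001", "b005 p006", "b009 p011"))))
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("guild mean comparison handles empty and single-cell input", {
  empty <- data.frame(node_a = character(0), node_b = character(0),
                      mic_e = numeric(0), tic_e = numeric(0),
                      rho = numeric(0), n = integer(0),
                      significant = logical(0), guild_a = character(0),
                      class_b = character(0))
  g0 <- guild_mean_comparison(empty)
  expect_false(g0$evaluable)
  one <- data.frame(node_a = paste0("b", 1:4), node_b = paste0("p", 1:4),
                    mic_e = 0.5, tic_e = 1, rho = c(0.4, 0.5, 0.6, 0.7),
                    n = 100, significant = TRUE, guild_a = "MRG",
                    class_b = "HiDP")
  g1 <- guild_mean_comparison(one)
  expect_false(g1$evaluable)
  expect_equal(g1$top_cell, "MRG:HiDP")
  expect_null(g1$comparison)
})

test_that("only significant positive correlations enter the cell means", {
  e <- data.frame(node_a = rep(paste0("b", 1:4), 2),
                  node_b = rep(paste0("p", 1:4), each = 2),
                  mic_e = 0.5, tic_e = 1,
                  rho = c(0.5, -0.5, 0.4, 0.3, 0.2, 0.6, 0.1, 0.25),
                  n = 100,
                  significant = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                                  TRUE, TRUE),
                  guild_a = rep(c("MRG", "nonMRG"), 4),
                  class_b = rep(c("HiDP", "NoDP"), each = 4))
  g <- guild_mean_comparison(e, min_cell = 1)
  used <- e$significant & e$rho > 0
  expect_equal(sum(g$cells$n_edges), sum(used))
})

test_that("graphml export round-trips nodes and attributes", {
  e <- data.frame(node_a = c("b1", "b2"), node_b = c("p1", "p1"),
                  mic_e = c(0.3, 0.4), tic_e = c(1, 2),
                  rho = c(0.7, 0.8), n = 50, significant = TRUE,
                  guild_a = "MRG", class_b = "HiDP")
  f <- tempfile(fileext = ".graphml")
  write_graphml(e, f, abundance = c(b1 = 0.1, b2 = 0.2, p1 = 0.3))
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(sort(igraph::E(g)$rho), c(0.7, 0.8))
  f2 <- tempfile(fileext = ".graphml")
  write_graphml(e[0, ], f2)
  g2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::ecount(g2), 0)
})
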