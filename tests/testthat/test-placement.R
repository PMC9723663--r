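make_symmetric_ref <- function(seq_len = 40) {
  # 4-tip tree with all branch lengths zero and identical tip sequences:
  # every attachment point is equivalent by construction
  tree <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  s <- sample(c("A", "C", "G", "T"), seq_len, TRUE)
  aln <- matrix(rep(s, 4), nrow = 4, byrow = TRUE,
                dimnames = list(c("A", "B", "C", "D"), NULL))
  traits <- setNames(rep("producer", 4), c("A", "B", "C", "D"))
  reference_phylogeny(tree, aln, traits)
}

test_that("like-weight ratios form a probability distribution over edges", {
  rs <- generate_reference_set(n_refs = 6, divergence_levels = 0.05,
                               seed = 21, seq_length = 120,
                               queries_per_level = 3)
  for (i in 1:3) {
    p <- place_query(as.character(rs$queries[[i]]), rs$phylogeny)
    expect_equal(sum(p$edges$lwr), 1, tolerance = 1e-9)
    expect_equal(p$best_loglik, max(p$edges$loglik))
  }
})

test_that("identical tips and query spread like-weight uniformly", {
  set.seed(22)
  ref <- make_symmetric_ref()
  q <- paste(ref$alignment[1, ], collapse = "")
  p <- place_query(q, ref)
  E <- nrow(p$edges)
  expect_equal(p$edges$lwr, rep(1 / E, E), tolerance = 1e-6)
})

test_that("a query copied from a tip places on that tip's pendant edge", {
  rs <- generate_reference_set(n_refs = 6, divergence_levels = 0.02,
                               seed = 23, seq_length = 200,
                               queries_per_level = 4)
  for (i in seq_len(4)) {
    q <- rs$queries[[i]]
    src <- rs$query_map$source_ref[i]
    p <- place_query(as.character(q), rs$phylogeny)
    src_tip <- match(src, rs$phylogeny$tree$tip.label)
    best_child <- p$edges$child[p$best_edge]
    expect_equal(best_child, src_tip)
    expect_gt(p$edges$lwr[p$best_edge], 0.9)
  }
})

test_that("per-edge log-likelihoods match the state-sum oracle", {
  set.seed(24)
  grid <- c(0.02, 0.15)
  for (r in 1:3) {
    tree <- ape::rtree(5, rooted = TRUE,
                       tip.label = sprintf("t%d", 1:5))
    tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.5)
    aln <- matrix(sample(c("A", "C", "G", "T"), 5 * 30, TRUE), nrow = 5,
                  dimnames = list(tree$tip.label, NULL))
    ref <- reference_phylogeny(tree, aln,
                               setNames(rep(c("producer", "nonproducer"),
                                            c(3, 2)), tree$tip.label))
    q <- sample(c("A", "C", "G", "T"), 30, TRUE)
    p <- place_query(paste(q, collapse = ""), ref, pendant_grid = grid)
    for (e in seq_len(nrow(p$edges))) {
      want <- oracle_attachment_ll(ref, q, e, grid)
      expect_equal(p$edges$loglik[e], want, tolerance = 1e-6)
    }
  }
})

test_that("placement is invariant to reference tip input order", {
  rs <- generate_reference_set(n_refs = 6, divergence_levels = 0.05,
                               seed = 25, seq_length = 100,
                               queries_per_level = 1)
  ref <- rs$phylogeny
  perm <- sample(rownames(ref$alignment))
  ref2 <- reference_phylogeny(ref$tree, ref$alignment[perm, ],
                              ref$traits[perm], ref$genus[perm])
  q <- as.character(rs$queries[[1]])
  expect_equal(place_query(q, ref)$edges$loglik,
               place_query(q, ref2)$edges$loglik, tolerance = 1e-12)
})

test_that("an all-gap query is unplaceable", {
  rs <- generate_reference_set(n_refs = 4, divergence_levels = 0,
                               seed = 26, seq_length = 50,
                               queries_per_level = 1)
  expect_error(place_query(strrep("-", 50), rs$phylogeny), "unplaceable")
})

test_that("trait gating is monotone in the posterior threshold", {
  rs <- generate_reference_set(n_refs = 8, divergence_levels = c(0.03, 0.1),
                               seed = 27, seq_length = 150,
                               queries_per_level = 3)
  thresholds <- c(0.5, 0.7, 0.9, 0.99)
  for (i in seq_along(rs$queries)) {
    p <- place_query(as.character(rs$queries[[i]]), rs$phylogeny)
    st <- vapply(thresholds, function(th)
      assign_producer_status(p, rs$phylogeny, posterior_threshold = th), "")
    classified <- st != "unclassified"
    # once unclassified at some threshold, never classified at a higher one
    expect_true(all(diff(as.integer(classified)) <= 0))
  }
  # enabling the log-likelihood gate can only unclassify
  p <- place_query(as.character(rs$queries[[1]]), rs$phylogeny)
  st_open <- assign_producer_status(p, rs$phylogeny)
  st_gated <- assign_producer_status(p, rs$phylogeny,
                                     loglik_ceiling = p$best_loglik - 1)
  expect_identical(st_gated, "unclassified")
  expect_true(st_open %in% c("producer", "nonproducer", "unclassified"))
})

test_that("queries from producer clades recover their trait", {
  recovered <- 0; total <- 0
  for (s in 1:20) {
    rs <- generate_reference_set(n_refs = 8, divergence_levels = 0.05,
                                 seed = 300 + s, seq_length = 200,
                                 queries_per_level = 4)
    for (i in seq_along(rs$queries)) {
      p <- place_query(as.character(rs$queries[[i]]), rs$phylogeny)
      st <- assign_producer_status(p, rs$phylogeny)
      total <- total + 1
      if (st == rs$query_map$true_trait[i]) recovered <- recovered + 1
    }
  }
  expect_gte(recovered / total, 0.95)
})

test_that("producer grading follows the 50 mM split and table coverage", {
  tab <- data.frame(genus = c("Micromonas", "Thalassiosira", "Edgecase"),
                    dmsp_mM = c(161.9, 10, 50))
  expect_equal(classify_production_level("producer", "Micromonas", tab),
               "HiDP")
  expect_equal(classify_production_level("producer", "Thalassiosira", tab),
               "LoDP")
  expect_equal(classify_production_level("producer", "Ostreococcus", tab),
               "UnDP")
  expect_equal(classify_production_level("nonproducer", "Micromonas", tab),
               "NoDP")
  expect_equal(classify_production_level("unclassified", "Micromonas", tab),
               "unclassified")
  expect_message(
    hit <- classify_production_level("producer", "Edgecase", tab),
    "split")
  expect_equal(hit, "HiDP")
  expect_equal(classify_production_level("producer", "Edgecase", tab,
                                         equal_side = "LoDP"),
               "LoDP")
})

test_that("classification partitions the query set", {
  rs <- generate_reference_set(n_refs = 8, divergence_levels = c(0.03, 0.08),
                               seed = 28, seq_length = 150,
                               queries_per_level = 4)
  cls <- classify_queries(rs$queries, rs$phylogeny, rs$genus_table,
                          query_genus = setNames(rs$query_map$genus,
                                                 rs$query_map$query_id))
  counts <- table(factor(cls$producer_class,
                         levels = c("HiDP", "LoDP", "UnDP", "NoDP",
                                    "unclassified")))
  expect_equal(sum(counts), length(rs$queries))
  expect_setequal(cls$query_id, names(rs$queries))
})

test_that("query alignment projects onto reference columns", {
  rs <- generate_reference_set(n_refs = 5, divergence_levels = 0.05,
                               seed = 29, seq_length = 80,
                               queries_per_level = 1)
  q <- as.character(rs$queries[[1]])
  aligned <- align_to_reference(q, rs$phylogeny)
  expect_equal(nchar(aligned), 80)
  expect_equal(aligned, q)      # indel-free query: projection is identity
  # a query with an internal deletion keeps reference coordinates: same
  # width, and the projected residues form a subsequence of the query
  # (residues falling on insert states are dropped, as in profile
  # alignment)
  qdel <- paste0(substr(q, 1, 30), substr(q, 41, 80))
  aligned_del <- align_to_reference(qdel, rs$phylogeny)
  expect_equal(nchar(aligned_del), 80)
  proj <- gsub("-", "", aligned_del)
  expect_gte(nchar(proj), 65)
  is_subseq <- grepl(paste(strsplit(proj, "")[[1]], collapse = ".*"), qdel)
  expect_true(is_subseq)
})

test_that("jplace export is valid JSON with normalised weights", {
  rs <- generate_reference_set(n_refs = 5, divergence_levels = 0.05,
                               seed = 30, seq_length = 80,
                               queries_per_level = 2)
  pls <- lapply(seq_along(rs$queries), function(i) {
    p <- place_query(as.character(rs$queries[[i]]), rs$phylogeny)
    p$query_id <- names(rs$queries)[i]
    p
  })
  f <- tempfile(fileext = ".jplace")
  write_jplace(pls, rs$phylogeny, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$version, 3)
  expect_length(j$placements, 2)
  lwrs <- vapply(j$placements[[1]]$p, function(rec) rec[[3]], numeric(1))
  expect_equal(sum(lwrs), 1, tolerance = 1e-9)
})
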