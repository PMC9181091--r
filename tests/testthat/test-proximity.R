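test_that("closest proximity on a path graph matches hand values", {
  g <- path_graph()
  expect_equal(closest_proximity(g, "A", "E"), 4)
  expect_equal(closest_proximity(g, c("A", "B"), c("A", "B")), 0)
  expect_equal(closest_proximity(g, c("A", "E"), "C"), 2)   # (2+2)/2
  expect_error(closest_proximity(g, character(0), "C"), "empty")
  expect_error(closest_proximity(g, "Q", "C"), "Q")
})

test_that("closest proximity agrees with the Floyd-Warshall oracle, with and without the distance cache", {
  withr::with_seed(13, {
    for (rep in 1:40) {
      n <- sample(5:50, 1)
      fx <- random_graph_fixture(n)
      g <- suppressMessages(largest_connected_component(
        suppressMessages(load_edge_list(fx$path))))
      nodes <- graph_nodes(g)
      if (length(nodes) < 4) next
      D <- fw_distances(fx$nodes, fx$edges)
      cache <- precompute_distances(g)
      for (draw in 1:5) {
        targets <- sample(nodes, sample(1:3, 1))
        disease <- sample(nodes, sample(1:4, 1))
        want <- fw_closest_proximity(D, targets, disease)
        expect_equal(closest_proximity(g, targets, disease), want)
        expect_equal(closest_proximity(g, targets, disease,
                                       dist_cache = cache), want)
      }
    }
  })
})

test_that("permutation significance is seed-deterministic and bounded by the pseudocount", {
  fx <- withr::with_seed(17, random_graph_fixture(80, p_edge = 0.06))
  g <- suppressMessages(largest_connected_component(
    suppressMessages(load_edge_list(fx$path))))
  bins <- build_degree_bins(g, min_bin_size = 10)
  nodes <- graph_nodes(g)
  targets <- withr::with_seed(18, sample(nodes, 4))
  disease <- withr::with_seed(19, sample(nodes, 6))

  r1 <- suppressMessages(
    permutation_significance(g, bins, targets, disease, n_perm = 50, seed = 5))
  r2 <- suppressMessages(
    permutation_significance(g, bins, targets, disease, n_perm = 50, seed = 5))
  expect_identical(r1, r2)
  expect_gt(r1$p_emp, 0)
  expect_lte(r1$p_emp, 1)
  expect_gte(r1$p_emp, 1 / 51)   # pseudocount floor

  # targets sitting inside the disease set: d_obs = 0 beats every non-zero
  # null draw, so p hits the floor exactly unless a null draw also hits 0
  r0 <- suppressMessages(
    permutation_significance(g, bins, disease[1:3], disease,
                             n_perm = 99, seed = 7))
  expect_equal(r0$d_obs, 0)
  expect_lte(r0$p_emp, (sum(r0$d_obs == 0) + 99 * 0.5) / 100)
})

test_that("a degenerate null with zero spread reports z = 0 with a warning", {
  # disease set = whole (complete) graph: every draw is forced to the same
  # node set, so d is 0 for observed and all permutations
  f <- tempfile()
  writeLines(c("A B", "A C", "A D", "B C", "B D", "C D"), f)
  g <- suppressMessages(load_edge_list(f))
  bins <- build_degree_bins(g, min_bin_size = 1)
  expect_warning(
    r <- suppressMessages(
      permutation_significance(g, bins, "A", c("A", "B", "C", "D"),
                               n_perm = 20, seed = 1)),
    "zero spread")
  expect_equal(r$z, 0)
  expect_equal(r$d_obs, 0)
  expect_equal(r$p_emp, 1)   # all null draws tie the observed value
})

test_that("similarity is the batch min-max rescale with the degenerate all-ones rule", {
  df <- data.frame(drug_id = c("a", "b", "c"), d_closest = c(1, 2, 3))
  out <- normalize_similarity(df)
  expect_equal(out$similarity, c(1, 0.5, 0))

  # all equal -> all 1
  df2 <- data.frame(drug_id = c("a", "b"), d_closest = c(2, 2))
  expect_equal(normalize_similarity(df2)$similarity, c(1, 1))

  # idempotent and order-invariant; anti-monotone in distance
  out2 <- normalize_similarity(out)
  expect_equal(out2$similarity, out$similarity)
  perm <- df[c(3, 1, 2), ]
  outp <- normalize_similarity(perm)
  expect_equal(outp$similarity[order(outp$drug_id)],
               out$similarity[order(out$drug_id)])
  expect_true(all(diff(out$similarity[order(out$d_closest)]) <= 0))
})

test_that("cluster adjustment follows the sigmoid boost/penalty rules", {
  df <- data.frame(drug_id = c("d1", "d2", "d3"),
                   disease_id = rep("MS", 3),
                   similarity = c(1, 0, 0.5))
  part <- c(d1 = 1L, d2 = 1L, d3 = 2L, MS = 1L)
  out <- cluster_adjust(df, part, steepness = 30, midpoint = 0.5)
  # same cluster, s = 1: s' = sigma(1) ~ 1
  expect_equal(out$similarity[1], 1 / (1 + exp(-30 * 0.5)), tolerance = 1e-12)
  expect_gt(out$similarity[1], 0.99)
  # s = 0 stays 0 regardless of cluster
  expect_equal(out$similarity[2], 0)
  # different cluster at the midpoint: s' = s / 2
  expect_equal(out$similarity[3], 0.25)

  expect_error(cluster_adjust(df, part[-1]), "missing cluster")
})

test_that("similarity communities feed cluster adjustment end to end", {
  df <- data.frame(drug_id = sprintf("d%d", 1:6),
                   disease_id = rep("MS", 6),
                   similarity = c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3))
  part <- detect_similarity_communities(df, seed = 2)
  expect_true(all(c(df$drug_id, "MS") %in% names(part)))
  out <- cluster_adjust(df, part)
  expect_true(all(out$similarity >= 0 & out$similarity <= 1))
})

test_that("score_all ranks planted drugs by proximity and is byte-reproducible", {
  cfg <- synthetic_config(n_nodes = 400, module_size = 12,
                          n_drugs_proximal = 3, n_drugs_random = 3,
                          targets_per_drug = 2, seed = 31)
  net <- generate_interactome(cfg)
  g <- net$graph
  bins <- build_degree_bins(g, min_bin_size = 20)

  # three drugs planted at increasing distance from the module
  pg <- plant_graded_drugs(g, net$module, n_drugs = 3, targets_per_drug = 1,
                           seed = 32)
  # plus one drug with no in-graph targets: excluded but counted
  drugs <- c(pg$drugs, list(DBX = drug_record("DBX", "ghost", "NOT_IN_GRAPH")))
  expect_message(
    res <- suppressMessages(score_all(g, bins, drugs, net$module,
                                      n_perm = 50, seed = 77)),
    NA)
  expect_equal(nrow(res), 3)
  expect_equal(attr(res, "n_excluded"), 1)
  expect_false("DBX" %in% res$drug_id)

  # similarity order matches the planted proximity order
  m <- merge(res, pg$truth, by = "drug_id")
  expect_equal(order(m$planted_distance), order(-m$similarity))
  expect_equal(m$d_closest, m$planted_distance)

  res2 <- suppressMessages(score_all(g, bins, drugs, net$module,
                                     n_perm = 50, seed = 77))
  attr(res, "n_excluded") <- NULL; attr(res2, "n_excluded") <- NULL
  expect_identical(res, res2)

  f1 <- tempfile(); f2 <- tempfile()
  write_scores(res, f1); write_scores(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("monotone recovery: planted distance rank anti-correlates with similarity rank", {
  cfg <- synthetic_config(n_nodes = 1000, module_size = 20, seed = 41)
  net <- generate_interactome(cfg)
  g <- net$graph
  bins <- build_degree_bins(g, min_bin_size = 50)
  pg <- plant_graded_drugs(g, net$module, n_drugs = 20, targets_per_drug = 1,
                           seed = 42)
  res <- suppressMessages(score_all(g, bins, pg$drugs, net$module,
                                    n_perm = 200, seed = 43))
  m <- merge(res, pg$truth, by = "drug_id")
  rho <- suppressWarnings(
    cor(m$planted_distance, m$similarity, method = "spearman"))
  expect_lte(rho, -0.9)
})
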