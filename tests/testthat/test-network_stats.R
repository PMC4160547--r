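test_that("community cohesion test flags a clique and ignores flat partitions", {
  # clique of 5 with one outgoing edge per node
  edges <- t(combn(paste0("K", 1:5), 2))
  edges <- rbind(edges, cbind(paste0("K", 1:5), paste0("O", 1:5)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  mod <- structure(list(subgraph = g, size = igraph::vcount(g)),
                   class = "module_result")
  part <- setNames(c(rep("core", 5), rep("rest", 5)),
                   c(paste0("K", 1:5), paste0("O", 1:5)))
  res <- community_significance(mod, part)
  p_core <- res$pval[res$community == "core"]
  expect_lt(p_core, 0.05)
  # oracle: exact one-sided rank-sum for (4,4,4,4,4) vs (1,1,1,1,1)
  p_exact <- stats::wilcox.test(rep(4, 5), rep(1, 5),
                                alternative = "greater",
                                exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_core, p_exact, tolerance = 1e-12)

  # identical within and between degrees carry no evidence: p = 1
  # (ring of 4 split into adjacent pairs: every node has within = between = 1)
  ring <- igraph::make_ring(4)
  igraph::V(ring)$name <- paste0("R", 1:4)
  mod_r <- structure(list(subgraph = ring, size = 4),
                     class = "module_result")
  part_r <- setNames(c("a", "a", "b", "b"), paste0("R", 1:4))
  res_r <- community_significance(mod_r, part_r)
  expect_true(all(res_r$pval == 1))

  # singleton community is untestable; uncovered node errors
  part_s <- part; part_s["K1"] <- "solo"
  res_s <- community_significance(mod, part_s)
  expect_equal(res_s$status[res_s$community == "solo"], "untestable")
  expect_error(community_significance(mod, part[-1]), "does not cover")
})

test_that("random balanced partitions of a random graph are not called cohesive", {
  # a random half of an ER graph has no internal structure; the one-sided
  # within > between test should fire at most at the nominal rate (it is in
  # fact conservative there: between-degrees draw from one extra node)
  set.seed(23)
  hits <- 0L; n_draw <- 120
  g <- igraph::sample_gnp(24, 0.25)
  igraph::V(g)$name <- sprintf("N%02d", 1:24)
  mod <- structure(list(subgraph = g, size = 24), class = "module_result")
  for (i in seq_len(n_draw)) {
    half <- sample(igraph::V(g)$name, 12)
    part <- setNames(ifelse(igraph::V(g)$name %in% half, "a", "b"),
                     igraph::V(g)$name)
    res <- community_significance(mod, part)
    hits <- hits + sum(res$pval < 0.05, na.rm = TRUE)
  }
  expect_lt(hits / (2 * n_draw), 0.1)
})

test_that("degree-binned permutation conserves degrees and the p multiset", {
  set.seed(31)
  g <- igraph::sample_pa(60, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("N%02d", 1:60)
  pv <- setNames(runif(60), igraph::V(g)$name)
  before <- igraph::degree(g)
  perm <- degree_binned_permutation(g, pv, n_bins = 10, seed = 4)
  expect_identical(igraph::degree(g), before)     # topology untouched
  expect_equal(sort(unname(perm)), sort(unname(pv)))  # multiset conserved
  # n_bins = 1 is a plain shuffle
  perm1 <- degree_binned_permutation(g, pv, n_bins = 1, seed = 4)
  expect_equal(sort(unname(perm1)), sort(unname(pv)))

  # a hub in its own bin is a fixed point
  star <- igraph::make_star(12, mode = "undirected")
  igraph::V(star)$name <- c("HUB", sprintf("L%02d", 1:11))
  pv_s <- setNames(seq(0.01, 0.12, by = 0.01), igraph::V(star)$name)
  for (s in 1:10) {
    p2 <- degree_binned_permutation(star, pv_s, n_bins = 8, seed = s)
    expect_equal(unname(p2["HUB"]), unname(pv_s["HUB"]))
  }
})

test_that("edge significance uses the pseudo-count convention", {
  set.seed(47)
  co <- simulate_cohort(sim_config(n_patients = 150, n_genes = 80,
                                   module_size = 6, beta = 2,
                                   lambda_mod = 0.6, seed = 2))
  sc <- cox_lrt_per_gene(co$bundle)
  ref <- search_fixed_size(sc, co$bundle$graph, 6)
  es <- edge_significance(co$bundle, sc, ref, R = 8, seed = 5)
  expect_true(all(es$edges$pval >= 1 / 9 - 1e-12))
  expect_true(all(es$edges$pval <= 1))
  expect_gt(es$aggregated_pval, 0)
  expect_lte(es$aggregated_pval, 1)
  expect_equal(es$R, 8)
  # p = (1 + hits)/(1 + R): an edge absent from every null module
  expect_true(any(abs(es$edges$pval - 1 / 9) < 1e-12))
})

test_that("leave-one-type-out confidence favours planted edges", {
  set.seed(59)
  co <- simulate_cohort(sim_config(n_patients = 360, n_genes = 100,
                                   module_size = 8, beta = 2,
                                   lambda_mod = 0.6, seed = 8))
  sc <- cox_lrt_per_gene(co$bundle)
  ref <- search_fixed_size(sc, co$bundle$graph, 8)
  conf <- loo_edge_confidence(co$bundle, ref)
  expect_true(all(conf$confidence >= 0 & conf$confidence <= 1))
  planted_keys <- apply(co$planted_edges, 1,
                        function(x) paste(sort(x), collapse = "|"))
  got_keys <- paste(pmin(conf$gene1, conf$gene2),
                    pmax(conf$gene1, conf$gene2), sep = "|")
  is_planted <- got_keys %in% planted_keys
  if (any(is_planted) && any(!is_planted)) {
    expect_gte(mean(conf$confidence[is_planted]),
               mean(conf$confidence[!is_planted]))
  }
  # with the strong evenly-spread signal most planted edges persist
  expect_gt(mean(conf$confidence[is_planted]), 0.5)
})

test_that("Fisher aggregation has its closed-form identities", {
  for (p in c(0.001, 0.2, 0.77))
    expect_equal(fisher_aggregate(p), p, tolerance = 1e-12)
  expect_equal(fisher_aggregate(rep(1, 5)), 1)
  expect_equal(fisher_aggregate(c(0.01, 0.02, 0.5)),
               0.00526255252558034, tolerance = 1e-12)
  # monotone: shrinking any component never raises the aggregate
  set.seed(13)
  for (i in 1:25) {
    p <- runif(sample(2:6, 1))
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- p[j] / 2
    expect_lte(fisher_aggregate(p2), fisher_aggregate(p))
  }
  expect_error(fisher_aggregate(numeric(0)), "empty")
  expect_error(fisher_aggregate(c(0.5, 0)), "must lie")
})
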