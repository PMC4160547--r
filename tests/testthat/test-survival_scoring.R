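test_that("per-gene Cox LRT matches a brute-force partial-likelihood oracle", {
  sim <- simulate_single_gene(n = 120, beta = 1, seed = 7)
  counts <- matrix(sim$x, ncol = 1,
                   dimnames = list(sprintf("P%03d", seq_along(sim$x)), "GX"))
  clin <- data.frame(patient = rownames(counts), time = sim$time,
                     event = sim$event, age = 60, gender = "female",
                     tumour_type = "T1", stringsAsFactors = FALSE)
  b <- suppressWarnings(make_bundle(counts, clin, path_graph(c("GX", "GY"))))
  sc <- suppressWarnings(cox_lrt_per_gene(b))
  beta_hat <- log(sc$hr[sc$gene == "GX"])
  beta_oracle <- oracle_cox_beta(sim$time, sim$event, sim$x)
  expect_equal(beta_hat, beta_oracle, tolerance = 1e-4)
  expect_gte(sc$lrt_stat[1], 0)
})

test_that("planted effect is recovered and degenerate genes are flagged", {
  set.seed(5)
  n <- 200
  sim <- simulate_single_gene(n = n, beta = 1, seed = 21)
  counts <- cbind(GX = sim$x, GZ = 0L, G1 = rpois(n, 0.2))
  rownames(counts) <- sprintf("P%03d", 1:n)
  clin <- make_clinical(n, types = c("A", "B"))
  clin$time <- sim$time; clin$event <- sim$event
  b <- make_bundle(counts, clin, path_graph(colnames(counts)))
  sc <- cox_lrt_per_gene(b)
  expect_equal(sc$status[sc$gene == "GZ"], "skipped")  # all-zero vector
  expect_lt(abs(log(sc$hr[sc$gene == "GX"]) - 1), 0.35)
  # min_mutated filter
  counts2 <- counts; counts2[, "G1"] <- c(1L, rep(0L, n - 1))
  sc2 <- cox_lrt_per_gene(make_bundle(counts2, clin,
                                      path_graph(colnames(counts))),
                          min_mutated = 2)
  expect_equal(sc2$status[sc2$gene == "G1"], "skipped")
})

test_that("null genes keep type-I error near the nominal level", {
  set.seed(11)
  n <- 200; n_genes <- 120
  sim <- simulate_single_gene(n = n, beta = 0, seed = 31)
  counts <- matrix(rpois(n * n_genes, 0.4), n,
                   dimnames = list(sprintf("P%03d", 1:n),
                                   sprintf("G%03d", 1:n_genes)))
  clin <- make_clinical(n, types = c("A", "B"))
  clin$time <- sim$time; clin$event <- sim$event
  b <- make_bundle(counts, clin, path_graph(colnames(counts)))
  sc <- cox_lrt_per_gene(b)
  frac <- mean(sc$pval[sc$status == "ok"] < 0.05)
  expect_lt(abs(frac - 0.05), 0.06)
})

test_that("combination curve reduces to the single fit at k=1 and aggregates counts", {
  set.seed(3)
  n <- 150
  counts <- cbind(GA = rpois(n, 0.4), GB = rpois(n, 0.4),
                  GC = rpois(n, 0.3))
  rownames(counts) <- sprintf("P%03d", 1:n)
  clin <- make_clinical(n, types = c("A", "B"),
                        time = rexp(n, 0.01), event = rbinom(n, 1, 0.7))
  b <- make_bundle(counts, clin, path_graph(colnames(counts)))
  sc <- cox_lrt_per_gene(b)
  cc <- cox_combination(b, sc, c("GA", "GB", "GC"))
  first <- cc$gene_added[1]
  expect_equal(cc$hr[1], sc$hr[sc$gene == first], tolerance = 1e-8)
  expect_equal(cc$gene_added, sc$gene[order(sc$pval, sc$gene)])
  # aggregated vector for disjoint genes is the elementwise sum
  agg <- rowSums(counts[, c("GA", "GB")])
  base <- survnet:::baseline_cox(b$clinical)
  direct <- survnet:::fit_gene_cox(base, agg)
  expect_equal(cc$hr[2], unname(direct["hr"]), tolerance = 1e-8)
  expect_error(cox_combination(b, sc, character(0)), "empty gene list")
})

test_that("combining weak planted genes beats most of them individually", {
  set.seed(17)
  wins <- 0L
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    n <- 250
    counts <- sapply(1:5, function(i) rpois(n, 0.4))
    colnames(counts) <- sprintf("M%d", 1:5)
    rownames(counts) <- sprintf("P%03d", 1:n)
    h <- 1e-3 * exp(0.4 * rowSums(counts))
    t_event <- rexp(n, h)
    clin <- make_clinical(n, types = c("A", "B"),
                          time = pmax(t_event, 1e-3), event = rep(1, n))
    b <- make_bundle(counts, clin, path_graph(colnames(counts)))
    sc <- cox_lrt_per_gene(b)
    cc <- cox_combination(b, sc, colnames(counts))
    if (isTRUE(cc$hr[5] > median(sc$hr))) wins <- wins + 1L
  }
  expect_gte(wins, round(0.85 * n_rep))
})

test_that("mutation frequency matches hand-computed fixtures", {
  counts <- rbind(c(1L, 0L), c(2L, 0L), c(0L, 0L),
                  c(0L, 1L), c(0L, 0L), c(3L, 1L))
  dimnames(counts) <- list(sprintf("P%03d", 1:6), c("GA", "GB"))
  clin <- make_clinical(6, types = c("GBM", "GBM", "GBM", "GBM", "OV", "OV"))
  b <- make_bundle(counts, clin, path_graph(c("GA", "GB")))
  f <- mutation_frequency(b)
  expect_equal(f["GA", "GBM"], 0.5)   # 2 of 4 GBM patients
  expect_equal(f["GB", "GBM"], 0.25)
  expect_equal(f["GA", "OV"], 0.5)
  expect_equal(f["GB", "OV"], 0.5)
  # all-zero gene gives a zero row
  counts0 <- cbind(counts, GC = 0L)
  f0 <- mutation_frequency(make_bundle(counts0, clin,
                                       path_graph(colnames(counts0))))
  expect_equal(unname(f0["GC", ]), c(0, 0))
})

test_that("mutation ubiquity follows its closed form and stays in [0,1]", {
  expect_equal(as.numeric(mutation_ubiquity(c(0.3, 0, 0, 0))), 0)
  for (n in c(2, 5, 11))
    expect_equal(mutation_ubiquity(rep(0.2, n)), 1)
  expect_equal(mutation_ubiquity(c(0.4, 0.1)),
               0.513450414233658, tolerance = 1e-12)
  # invariance to positive rescaling and permutation, range property
  set.seed(9)
  for (i in 1:50) {
    f <- runif(sample(2:8, 1))
    u <- mutation_ubiquity(f)
    expect_gte(u, 0); expect_lte(u, 1 + 1e-12)
    expect_equal(mutation_ubiquity(f * 0.5), u, tolerance = 1e-12)
    expect_equal(mutation_ubiquity(sample(f)), u, tolerance = 1e-12)
  }
  z <- mutation_ubiquity(c(0, 0, 0))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "all_zero"))
  expect_error(mutation_ubiquity(0.5), "at least 2")
})
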