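test_that("GSEA running score matches a naive reference and ends at zero", {
  set.seed(3)
  N <- 60
  metric <- sort(rexp(N), decreasing = TRUE)
  genes <- sprintf("G%03d", 1:N)
  ranked <- rank_by_metric(setNames(metric, genes))
  hit_set <- genes[c(1:5, 30, 50)]
  for (q in c(0, 1)) {
    res <- gsea(ranked, hit_set, q = q, R = 50, seed = 1)
    hit <- ranked$gene %in% hit_set
    ref <- oracle_gsea_running(ranked$metric, hit, q)
    expect_equal(res$running, ref, tolerance = 1e-12)
    expect_equal(res$running[N], 0, tolerance = 1e-12)
    expect_equal(res$es, ref[which.max(abs(ref))], tolerance = 1e-12)
    expect_equal(sign(res$nes), sign(res$es))
    expect_gt(res$pval, 0)
  }
  # a set occupying the top ranks maximises the running sum at rank m
  top <- genes[1:10]
  res_top <- gsea(ranked, top, q = 0, R = 50, seed = 2)
  expect_equal(res_top$peak_rank, 10)
  expect_equal(res_top$es, 1 - 0, tolerance = 1e-12)  # all hits before any miss
  expect_lt(res_top$pval, 0.05)
})

test_that("reversing the list negates the unweighted enrichment score", {
  set.seed(8)
  N <- 40
  genes <- sprintf("G%03d", 1:N)
  metric <- setNames(seq(N, 1), genes)
  ranked <- rank_by_metric(metric)
  rev_ranked <- ranked[rev(seq_len(N)), ]
  class(rev_ranked) <- class(ranked)
  set_g <- genes[1:8]
  a <- gsea(ranked, set_g, q = 0, R = 10, seed = 1)
  b <- gsea(rev_ranked, set_g, q = 0, R = 10, seed = 1)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
})

test_that("GSEA permutation p is calibrated under random sets", {
  set.seed(12)
  N <- 80
  genes <- sprintf("G%03d", 1:N)
  ranked <- rank_by_metric(setNames(rexp(N), genes))
  pvals <- vapply(1:60, function(i) {
    gsea(ranked, sample(genes, 8), q = 1, R = 100, seed = 1000 + i)$pval
  }, 0)
  expect_gt(mean(pvals), 0.25)          # not systematically anti-conservative
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_true(all(pvals > 0))
  expect_error(gsea(ranked, c("ZZZ"), R = 10), "disjoint")
})

test_that("rank builders are deterministic and flag constant metrics", {
  flat <- rank_by_metric(setNames(rep(1, 4), c("D", "B", "A", "C")))
  expect_equal(flat$gene, c("A", "B", "C", "D"))  # lexicographic tie rule
  expect_true(attr(flat, "untestable"))

  counts <- rbind(c(3L, 1L, 0L), c(0L, 2L, 5L), c(1L, 1L, 1L))
  dimnames(counts) <- list(sprintf("P%03d", 1:3), c("GA", "GB", "GC"))
  clin <- make_clinical(3, types = "T1")
  b <- suppressWarnings(make_bundle(counts, clin,
                                    path_graph(colnames(counts))))
  rl <- rank_builders(b)
  expect_equal(rl[["patient.P001"]]$gene, c("GA", "GB", "GC"))
  expect_equal(rl[["patient.P002"]]$gene, c("GC", "GB", "GA"))
  expect_equal(rl[["patient.P003"]]$gene, c("GA", "GB", "GC"))  # ties -> lexicographic
})

test_that("hypergeometric tail matches exact enumeration and Fisher's test", {
  background <- sprintf("B%03d", 1:50)
  group <- background[1:5]
  term <- background[c(1:4, 20:25)]
  res <- hypergeom_enrich(group, list(tm = term), background)
  # oracle: exact tail sum of the hypergeometric pmf
  K <- 10; N <- 50; n <- 5; k <- 4
  p_exact <- sum(dhyper(k:min(K, n), K, N - K, n))
  expect_equal(res$pval, p_exact, tolerance = 1e-12)
  # and the one-sided Fisher's exact p on the same 2x2 table
  tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2)
  expect_equal(res$pval, fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-10)
  # degenerate urn: term = group = background forces the overlap
  res1 <- hypergeom_enrich(background, list(all = background), background)
  expect_equal(res1$pval, 1)
  expect_true(all(res$fdr >= res$pval))
  expect_error(hypergeom_enrich(group, list(tm = term), character(0)),
               "empty background")
  expect_error(hypergeom_enrich(c(group, "XX"), list(tm = term), background),
               "outside background")
})

test_that("random terms stay unenriched after FDR control", {
  set.seed(21)
  background <- sprintf("B%03d", 1:200)
  sims <- vapply(1:40, function(i) {
    group <- sample(background, 15)
    terms <- lapply(1:20, function(j) sample(background, 12))
    names(terms) <- sprintf("t%02d", 1:20)
    min(hypergeom_enrich(group, terms, background)$fdr)
  }, 0)
  expect_gte(mean(sims > 0.05), 0.9)
})

test_that("ontology propagation is a monotone idempotent closure", {
  sets <- list(root = character(0), A = "g1", B = c("g2", "g3"))
  hier <- data.frame(parent = c("root", "A"), child = c("A", "B"))
  prop <- propagate_ontology(sets, hier)
  expect_setequal(prop$root, c("g1", "g2", "g3"))
  expect_setequal(prop$A, c("g1", "g2", "g3"))
  expect_identical(propagate_ontology(prop, hier)[order(names(prop))],
                   prop[order(names(prop))])
  # diamond DAG: both paths deliver the leaf annotation to the top
  dsets <- list(top = character(0), l = character(0), r = character(0),
                leaf = "gX")
  dhier <- data.frame(parent = c("top", "top", "l", "r"),
                      child = c("l", "r", "leaf", "leaf"))
  dprop <- propagate_ontology(dsets, dhier)
  expect_equal(dprop$top, "gX")
  expect_equal(dprop$l, "gX")
  expect_equal(dprop$r, "gX")
  # monotone growth: no annotation removed
  for (nm in names(sets))
    expect_true(all(sets[[nm]] %in% prop[[nm]]))
  cyc <- data.frame(parent = c("A", "B"), child = c("B", "A"))
  expect_error(propagate_ontology(sets, cyc), "cycle")
})

test_that("phylostratum enrichment concentrates where the genes were born", {
  # repertoire of an ancestor = genes already present in its genome,
  # i.e. those created at or before it (oldest has the smallest repertoire)
  strata <- c("Cellular", "Eukaryota", "Deuterostomia")
  reps <- list(Cellular = sprintf("g%03d", 1:30),
               Eukaryota = sprintf("g%03d", 1:60),
               Deuterostomia = sprintf("g%03d", 1:90))
  ages <- setNames(rep(strata, each = 30), sprintf("g%03d", 1:90))
  group <- sprintf("g%03d", 61:75)  # all born in Deuterostomia
  res <- phylostratum_enrich(group, ages, reps, strata)
  tab <- res$enrichment
  expect_equal(tab$term[which.min(tab$pval)], "Deuterostomia")
  expect_lt(min(tab$pval), 0.05)
  # cumulative fraction: 40% of group at the oldest stratum
  group2 <- c(sprintf("g%03d", 1:4), sprintf("g%03d", 31:36))
  res2 <- phylostratum_enrich(group2, ages, reps, strata)
  expect_equal(res2$enrichment$cumulative_fraction[1], 0.4)
  expect_equal(res2$enrichment$cumulative_fraction[3], 1)
  # unmapped genes are reported, not dropped silently
  res3 <- phylostratum_enrich(c(group, "unknown1"), ages, reps, strata)
  expect_equal(res3$unmapped, "unknown1")
})
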