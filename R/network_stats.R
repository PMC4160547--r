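#' Cohesion significance of module communities
#'
#' Community detection itself is delegated to any modularity-based algorithm
#' (e.g. [igraph::cluster_fast_greedy()] or spin-glass); the test implemented
#' here asks whether a community is more internally connected than externally:
#' for each community the per-node within-community degree is compared to the
#' per-node between-community degree by a one-sided Wilcoxon rank-sum test
#' (within > between). Exact enumeration is used for small tie-free samples,
#' the normal approximation with tie correction otherwise.
#'
#' @param module A `module_result`.
#' @param partition Named vector (node -> community label) covering all
#'   module nodes, or an igraph `communities` object.
#' @return Data frame with columns `community`, `n_nodes`, `pval`, `status`.
#' @export
community_significance <- function(module, partition) {
  sub <- module$subgraph
  if (inherits(partition, "communities"))
    partition <- stats::setNames(igraph::membership(partition),
                                 names(igraph::membership(partition)))
  nodes <- igraph::V(sub)$name
  missing_n <- setdiff(nodes, names(partition))
  if (length(missing_n))
    stop("partition does not cover module node(s): ",
         paste(missing_n, collapse = ", "))
  lab <- as.character(partition[nodes])
  adj <- igraph::as_adjacency_matrix(sub, sparse = FALSE)
  labs <- sort(unique(lab))
  res <- lapply(labs, function(cl) {
    inside <- lab == cl
    if (sum(inside) < 2)
      return(data.frame(community = cl, n_nodes = sum(inside),
                        pval = NA_real_, status = "untestable"))
    within <- rowSums(adj[inside, inside, drop = FALSE])
    between <- rowSums(adj[inside, !inside, drop = FALSE])
    data.frame(community = cl, n_nodes = sum(inside),
               pval = wilcox_greater(within, between), status = "ok")
  })
  do.call(rbind, res)
}

# One-sided Wilcoxon rank-sum p (x > y). Degenerate all-tied samples carry no
# evidence and return 1 explicitly (the normal approximation would be 0/0).
wilcox_greater <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  exact <- length(x) < 10 && length(y) < 10 && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                      exact = exact, correct = TRUE)$p.value)
}

#' Leave-one-tumour-type-out edge confidence
#'
#' Robustness of an identified module against dominance by any one tumour
#' type: each tumour type's patients are removed in turn, per-gene Cox scores
#' are recomputed, and a module of (approximately) the reference size is
#' re-identified. The confidence (bootstrap value) of a reference edge is the
#' fraction of removal runs whose module contains it.
#'
#' @param bundle A `survnet_bundle` (at least 2 tumour types).
#' @param reference The reference `module_result` whose edges are assessed.
#' @param min_mutated Passed to [cox_lrt_per_gene()].
#' @param tol,max_iter Passed to [search_fixed_size()].
#' @return Data frame `gene1`, `gene2`, `confidence`; attribute `"runs"`
#'   holds the per-type module node lists.
#' @export
loo_edge_confidence <- function(bundle, reference, min_mutated = 2,
                                tol = 2, max_iter = 30) {
  types <- levels(bundle$clinical$tumour_type)
  if (length(types) < 2) stop("need at least 2 tumour types for removal runs")
  ref_edges <- edge_keys(reference$subgraph)
  hits <- stats::setNames(numeric(length(ref_edges)), ref_edges)
  runs <- list()
  for (tt in types) {
    keep <- bundle$clinical$tumour_type != tt
    sub_bundle <- subset_bundle(bundle, keep)
    mod <- tryCatch({
      sc <- cox_lrt_per_gene(sub_bundle, min_mutated = min_mutated)
      search_fixed_size(sc, bundle$graph, target_size = reference$size,
                        tol = tol, max_iter = max_iter)
    }, error = function(e) NULL)
    if (is.null(mod)) {
      message("removal run without identifiable module (dropped ", tt, ")")
      runs[[tt]] <- character(0)
      next
    }
    runs[[tt]] <- igraph::V(mod$subgraph)$name
    found <- intersect(ref_edges, edge_keys(mod$subgraph))
    hits[found] <- hits[found] + 1
  }
  conf <- hits / length(types)
  ep <- do.call(rbind, strsplit(names(conf), "\r"))
  out <- data.frame(gene1 = ep[, 1L], gene2 = ep[, 2L],
                    confidence = unname(conf), stringsAsFactors = FALSE)
  attr(out, "runs") <- runs
  out
}

# canonical undirected edge keys (lexicographic endpoint order)
edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  e <- igraph::ends(g, igraph::E(g), names = TRUE)
  apply(e, 1L, function(x) paste(sort(x), collapse = "\r"))
}

subset_bundle <- function(bundle, keep) {
  mm <- unclass(bundle$mutations)[keep, , drop = FALSE]
  class(mm) <- c("mutation_matrix", class(mm))
  clin <- bundle$clinical[keep, , drop = FALSE]
  clin$tumour_type <- droplevels(clin$tumour_type)
  clin$gender <- droplevels(clin$gender)
  rownames(clin) <- NULL
  out <- list(mutations = mm, clinical = clin, graph = bundle$graph)
  class(out) <- "survnet_bundle"
  out
}

#' Degree-binned permutation of gene labels
#'
#' The degree-approximating randomisation null: gene p-value labels are
#' shuffled only among nodes of similar degree, so the permuted data keep the
#' network topology and (approximately) the degree-to-significance coupling.
#' Nodes are partitioned into `n_bins` log2-spaced degree bins and labels are
#' permuted uniformly within each bin; with `n_bins = 1` this is a plain
#' label shuffle. The degree sequence and the multiset of p-values are both
#' conserved exactly.
#'
#' @param graph An `igraph` network.
#' @param pvals Named numeric vector gene -> p-value (genes not in `pvals`
#'   carry `NA` and are shuffled as such).
#' @param n_bins Number of log2 degree bins (default 10).
#' @param seed Optional integer seed (applied locally, never global state).
#' @return Named numeric vector: permuted gene -> p-value over graph nodes.
#' @export
degree_binned_permutation <- function(graph, pvals, n_bins = 10, seed = NULL) {
  stopifnot(n_bins >= 1)
  nodes <- igraph::V(graph)$name
  if (!length(nodes)) return(stats::setNames(numeric(0), character(0)))
  p <- unname(pvals[nodes])
  deg <- igraph::degree(graph)
  ld <- log2(deg)
  if (n_bins == 1L || length(unique(ld)) == 1L) {
    bin <- rep(1L, length(nodes))
  } else {
    brk <- seq(min(ld), max(ld), length.out = n_bins + 1L)
    bin <- cut(ld, breaks = brk, include.lowest = TRUE, labels = FALSE)
  }
  do_perm <- function() {
    out <- p
    for (b in unique(bin)) {
      idx <- which(bin == b)
      if (length(idx) > 1L) out[idx] <- p[sample(idx)]
    }
    stats::setNames(out, nodes)
  }
  if (is.null(seed)) do_perm() else withr::with_seed(seed, do_perm())
}

#' Empirical edge significance under degree-binned randomisation
#'
#' Repeats `R` times: permute the gene p-value labels with
#' [degree_binned_permutation()], re-identify a module of the reference size,
#' and record its edges. Each reference edge's empirical p-value is
#' `(1 + number of null modules containing it) / (1 + R)` (pseudo-count, so p
#' is never exactly 0); the per-edge p-values are combined over all reference
#' edges with [fisher_aggregate()].
#'
#' @param bundle A `survnet_bundle`.
#' @param scores The observed `gene_score_table`.
#' @param reference The reference `module_result`.
#' @param R Number of randomisations (default 100).
#' @param n_bins Degree bins for the permutation (default 10).
#' @param seed Integer seed.
#' @param tol,max_iter Passed to [search_fixed_size()].
#' @return List of class `edge_significance`: `edges` (data frame `gene1`,
#'   `gene2`, `pval`), `aggregated_pval`, `R`.
#' @export
edge_significance <- function(bundle, scores, reference, R = 100,
                              n_bins = 10, seed = NULL, tol = 2,
                              max_iter = 30) {
  stopifnot(R >= 1)
  ref_edges <- edge_keys(reference$subgraph)
  hits <- stats::setNames(numeric(length(ref_edges)), ref_edges)
  pv <- stats::setNames(scores$pval, scores$gene)
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max %/% 2, R)
           else seed + seq_len(R)
  for (r in seq_len(R)) {
    perm <- degree_binned_permutation(bundle$graph, pv, n_bins = n_bins,
                                      seed = seeds[r])
    null_scores <- data.frame(gene = names(perm), pval = unname(perm),
                              stringsAsFactors = FALSE)
    mod <- tryCatch(
      search_fixed_size(null_scores, bundle$graph,
                        target_size = reference$size,
                        tol = tol, max_iter = max_iter),
      error = function(e) NULL)
    if (is.null(mod)) next  # failed null run contributes no edges
    found <- intersect(ref_edges, edge_keys(mod$subgraph))
    hits[found] <- hits[found] + 1
  }
  p_edge <- (1 + hits) / (1 + R)
  ep <- do.call(rbind, strsplit(names(p_edge), "\r"))
  edges <- data.frame(gene1 = ep[, 1L], gene2 = ep[, 2L],
                      pval = unname(p_edge), stringsAsFactors = FALSE)
  structure(list(edges = edges,
                 aggregated_pval = fisher_aggregate(edges$pval),
                 R = R),
            class = "edge_significance")
}

#' Combine p-values by Fisher's method
#'
#' `X = -2 * sum(log(p))` is referred to the upper tail of a chi-squared
#' distribution with `2k` degrees of freedom. A single p-value is returned
#' unchanged (the chi-squared tail is then the identity). Smaller component
#' p-values never increase the aggregate.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return The aggregated p-value.
#' @export
fisher_aggregate <- function(pvals) {
  if (!length(pvals)) stop("empty p-value list")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(pvals))
  stats::pchisq(X, df = 2 * length(pvals), lower.tail = FALSE)
}
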