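#' Transform p-values into signed node scores on the network
#'
#' Given a tolerable p-value threshold `tau`, each scored gene gets
#' `s = log10(tau) - log10(max(p, 1e-300))`: positive below the threshold
#' (a node of interest), zero at the boundary, negative above it
#' (tolerated only as a linker). Graph nodes without a usable p-value
#' (unscored, skipped or failed fits) are assigned the median negative score
#' of the scored intolerable nodes, so well-connected hubs can still serve as
#' linkers. The graph is restricted to its largest connected component.
#'
#' @param scores A `gene_score_table` from [cox_lrt_per_gene()] (or any data
#'   frame with `gene` and `pval` columns).
#' @param graph An `igraph` gene network.
#' @param pcut P-value threshold `tau` in (0, 1).
#' @return An `igraph` of class `scored_graph` with vertex attributes `score`
#'   and `pval` and graph attribute `tau`.
#' @export
score_nodes <- function(scores, graph, pcut = 0.05) {
  stopifnot(pcut > 0, pcut < 1)
  pv <- scores$pval[match(igraph::V(graph)$name, scores$gene)]
  if (all(is.na(pv))) stop("no scored genes present in the network")
  s <- log10(pcut) - log10(pmax(pv, 1e-300))
  if (!any(s > 0, na.rm = TRUE))
    stop("no nodes of interest at this threshold")
  neg <- s[!is.na(s) & s <= 0]
  filler <- if (length(neg)) stats::median(neg) else 0
  s[is.na(s)] <- filler
  g <- graph
  igraph::V(g)$score <- s
  igraph::V(g)$pval <- pv
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, keep)
  if (!any(igraph::V(g)$score > 0))
    stop("no nodes of interest at this threshold (largest component)")
  g <- igraph::set_graph_attr(g, "tau", pcut)
  class(g) <- c("scored_graph", class(g))
  g
}

#' Extract the maximum-scoring connected subgraph
#'
#' Deterministic minimum-spanning-tree heuristic for the node-weighted
#' prize-collecting Steiner tree problem:
#' 1. each edge gets cost `max(-s(u),0)/2 + max(-s(v),0)/2 + 1e-9`;
#' 2. all-pairs shortest paths among positive-score nodes under that cost
#'    (the metric closure);
#' 3. minimum spanning tree of the closure;
#' 4. closure edges are expanded back to their underlying paths and unioned;
#' 5. the union is reduced to a spanning tree and the maximum-score connected
#'    subtree is extracted exactly by dynamic programming (which subsumes
#'    iterative pruning of non-positive leaves);
#' 6. the result is compared against the best single positive node and the
#'    higher-scoring of the two is returned.
#'
#' Ties are broken lexicographically by node identifier, so identical inputs
#' always yield identical modules.
#'
#' @param sg A `scored_graph` from [score_nodes()].
#' @return A list of class `module_result`: `subgraph` (connected `igraph`),
#'   `score` (sum of member node scores), `tau`, `size`, and a `nodes` data
#'   frame of per-member score and p-value.
#' @export
max_scoring_subgraph <- function(sg) {
  s <- igraph::V(sg)$score
  names(s) <- igraph::V(sg)$name
  pos <- which(s > 0)
  if (!length(pos)) stop("no positive-score nodes")
  ec <- igraph::ends(sg, igraph::E(sg), names = FALSE)
  cost <- pmax(-s[ec[, 1L]], 0) / 2 + pmax(-s[ec[, 2L]], 0) / 2 + 1e-9
  best_single <- pos[order(-s[pos], names(s)[pos])][1L]

  members <- if (length(pos) == 1L) {
    best_single
  } else {
    d <- igraph::distances(sg, v = pos, to = pos, weights = cost)
    d[lower.tri(d)] <- t(d)[lower.tri(d)]  # exact symmetry despite FP noise
    closure <- igraph::graph_from_adjacency_matrix(
      d, mode = "undirected", weighted = TRUE, diag = FALSE)
    mst <- igraph::mst(closure, weights = igraph::E(closure)$weight)
    mst_ends <- igraph::ends(mst, igraph::E(mst), names = TRUE)
    vids <- integer(0)
    for (r in seq_len(nrow(mst_ends))) {
      sp <- igraph::shortest_paths(
        sg,
        from = which(igraph::V(sg)$name == mst_ends[r, 1L]),
        to = which(igraph::V(sg)$name == mst_ends[r, 2L]),
        weights = cost, output = "vpath")
      vids <- union(vids, as.integer(sp$vpath[[1L]]))
    }
    best_subtree(sg, vids, cost)
  }

  mod_score <- sum(s[members])
  if (mod_score < s[best_single]) members <- best_single
  sub <- igraph::induced_subgraph(sg, members)
  class(sub) <- setdiff(class(sub), "scored_graph")
  structure(list(
    subgraph = sub,
    score = sum(igraph::V(sub)$score),
    tau = igraph::graph_attr(sg, "tau"),
    size = igraph::vcount(sub),
    nodes = data.frame(gene = igraph::V(sub)$name,
                       score = igraph::V(sub)$score,
                       pval = igraph::V(sub)$pval,
                       stringsAsFactors = FALSE)
  ), class = "module_result")
}

# Reduce the union of expanded paths to a spanning tree (under the same edge
# costs), then extract its maximum-score connected subtree exactly: rooted
# post-order DP with best(v) = s(v) + sum over children of max(best(child), 0);
# the optimum subtree's topmost node attains the global maximum. Returns the
# member indices in sg. A retained leaf always has positive score: a
# non-positive leaf's singleton subtree would have been dropped.
best_subtree <- function(sg, vids, cost) {
  sub <- igraph::induced_subgraph(sg, vids)
  s_sub <- igraph::V(sub)$score
  ee <- igraph::ends(sub, igraph::E(sub), names = FALSE)
  w <- pmax(-s_sub[ee[, 1L]], 0) / 2 + pmax(-s_sub[ee[, 2L]], 0) / 2 + 1e-9
  tree <- igraph::mst(sub, weights = w)
  n <- igraph::vcount(tree)
  if (n == 1L) return(vids)
  root <- 1L
  bf <- igraph::bfs(tree, root = root, father = TRUE, order = TRUE)
  ord <- as.integer(bf$order)
  father <- as.integer(bf$father)
  s_t <- igraph::V(tree)$score
  best <- s_t
  for (v in rev(ord)) {
    f <- father[v]
    if (!is.na(f) && best[v] > 0) best[f] <- best[f] + best[v]
  }
  top <- which.max(best)
  # collect: top plus every descendant chain with positive best
  keep <- logical(n)
  keep[top] <- TRUE
  for (v in ord) {
    f <- father[v]
    if (!is.na(f) && keep[f] && best[v] > 0 && v != top) keep[v] <- TRUE
  }
  keep_names <- igraph::V(tree)$name[keep]
  vids[igraph::V(sg)$name[vids] %in% keep_names]
}

#' @export
print.module_result <- function(x, ...) {
  cat("survnet module:", x$size, "nodes,",
      igraph::ecount(x$subgraph), "edges; total score",
      format(x$score, digits = 4), "at tau =", format(x$tau, digits = 3), "\n")
  invisible(x)
}

#' Search for a module of a requested size by threshold tuning
#'
#' Bisects over the ladder of candidate thresholds (midpoints between
#' consecutive distinct observed p-values) until the identified module's node
#' count is within `tol` of `target_size`; after `max_iter` iterations the
#' module minimising `|size - target_size|` is returned (ties resolved toward
#' the smaller, more stringent threshold). Module size is treated as
#' approximately monotone in the threshold.
#'
#' @param scores A `gene_score_table`.
#' @param graph An `igraph` gene network.
#' @param target_size Desired number of module nodes.
#' @param tol Acceptable deviation in nodes (default 2).
#' @param max_iter Maximum bisection steps (default 30).
#' @return A `module_result`; attribute `"warning"` is set when the target
#'   size is unreachable on this graph.
#' @export
search_fixed_size <- function(scores, graph, target_size, tol = 2,
                              max_iter = 30) {
  stopifnot(target_size >= 1)
  pv <- sort(unique(scores$pval[is.finite(scores$pval)]))
  if (!length(pv)) stop("no finite p-values to tune over")
  # thresholds sitting just above each distinct p-value, so ladder step k
  # admits exactly the k smallest p-value groups as positive nodes
  thr <- c((pv[-length(pv)] + pv[-1L]) / 2, min(1 - 1e-12, (pv[length(pv)] + 1) / 2))

  run_at <- function(tau) {
    tryCatch(max_scoring_subgraph(score_nodes(scores, graph, tau)),
             error = function(e) NULL)
  }

  lo <- 1L; hi <- length(thr)
  best <- NULL; best_gap <- Inf; best_idx <- Inf
  for (iter in seq_len(max_iter)) {
    if (lo > hi) break
    mid <- (lo + hi) %/% 2L
    mod <- run_at(thr[mid])
    size <- if (is.null(mod)) 0L else mod$size
    gap <- abs(size - target_size)
    if (!is.null(mod) &&
        (gap < best_gap || (gap == best_gap && mid < best_idx))) {
      best <- mod; best_gap <- gap; best_idx <- mid
    }
    if (!is.null(mod) && gap <= tol) return(mod)
    if (size < target_size) lo <- mid + 1L else hi <- mid - 1L
  }
  if (is.null(best)) {
    # fall back to scanning a coarse subset of the ladder
    for (i in unique(round(seq(1L, length(thr), length.out = min(20L, length(thr)))))) {
      mod <- run_at(thr[i])
      if (is.null(mod)) next
      gap <- abs(mod$size - target_size)
      if (gap < best_gap) { best <- mod; best_gap <- gap }
    }
  }
  if (is.null(best)) stop("no module identifiable at any threshold")
  if (best_gap > tol)
    attr(best, "warning") <- paste0("target size ", target_size,
                                    " unreachable; returned size ", best$size)
  best
}
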