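# Fixture builders and independent oracles used across the suite.

# tiny in-memory bundle from explicit pieces
make_bundle <- function(counts, clin_df, graph = NULL) {
  if (is.null(graph)) {
    graph <- igraph::make_ring(ncol(counts))
    igraph::V(graph)$name <- colnames(counts)
  }
  harmonise(as_mutation_matrix(counts), as_clinical(clin_df), graph)
}

# deterministic clinical frame: alternating genders, cyclic tumour types
make_clinical <- function(n, types = c("GBM", "OV"), time = NULL,
                          event = NULL) {
  data.frame(
    patient = sprintf("P%03d", seq_len(n)),
    time = if (is.null(time)) seq(10, 10 * n, by = 10) else time,
    event = if (is.null(event)) rep(c(1, 0), length.out = n) else event,
    age = 50 + seq_len(n) %% 20,
    gender = rep(c("male", "female"), length.out = n),
    tumour_type = rep(types, length.out = n),
    stringsAsFactors = FALSE)
}

path_graph <- function(names) {
  g <- igraph::make_ring(length(names), circular = FALSE)
  igraph::V(g)$name <- names
  g
}

# ---- independent oracles ------------------------------------------------

# Cox partial log-likelihood for a single covariate, no ties (Breslow =
# Efron when event times are distinct); maximised by golden-section search.
oracle_cox_beta <- function(time, event, x) {
  pll <- function(b) {
    eta <- x * b
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; eta <- eta[ord]
    # risk set of i: all j with time_j >= time_i
    rev_cumsum <- rev(cumsum(rev(exp(eta))))
    sum((eta - log(rev_cumsum))[event == 1])
  }
  stats::optimize(pll, c(-10, 10), maximum = TRUE)$maximum
}

# exhaustive maximum-scoring connected-subgraph search by bitmask BFS;
# adj is an n x n 0/1 matrix, s a score vector, n <= ~14
oracle_best_subgraph <- function(adj, s) {
  n <- length(s)
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) > 1) {
      # BFS connectivity within the subset
      seen <- members[1L]
      frontier <- members[1L]
      while (length(frontier)) {
        nb <- unique(unlist(lapply(frontier, function(v)
          members[adj[v, members] > 0])))
        frontier <- setdiff(nb, seen)
        seen <- union(seen, frontier)
      }
      if (length(seen) < length(members)) next
    }
    sc <- sum(s[members])
    if (sc > best) best <- sc
  }
  best
}

# naive GSEA running sum, written independently of running_es()
oracle_gsea_running <- function(metric, hit, q) {
  N <- length(hit)
  denom <- sum(abs(metric[hit])^q)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + abs(metric[i])^q / denom
           else cur - 1 / (N - sum(hit))
    run[i] <- cur
  }
  run
}

# small survival cohort with one planted gene and no covariate effects,
# suitable for beta-recovery checks
simulate_single_gene <- function(n = 200, beta = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- rpois(n, 0.5)
    h <- 1e-3 * exp(beta * x)
    t_event <- rexp(n, h)
    t_cens <- rexp(n, mean(h) * 0.25 / 0.75)
    list(time = pmax(pmin(t_event, t_cens), 1e-3),
         event = as.numeric(t_event <= t_cens), x = x)
  })
}
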