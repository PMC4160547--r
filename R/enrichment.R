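#' Pre-ranked gene set enrichment analysis
#'
#' Walks down a ranked gene list accumulating a running score: at each rank
#' belonging to the gene set the score increases by
#' `|metric|^q / sum over the set of |metric|^q` (at `q = 0` every hit counts
#' equally), and at every other rank it decreases by `1/(N - set size)`. The
#' enrichment score `es` is the extremum of largest absolute deviation
#' (signed); the running score starts and ends at 0. Significance comes from
#' `R` randomly sampled gene sets of the same size: the permutation p-value
#' uses the same-sign nulls with a pseudo-count, and the normalised enrichment
#' score is `es` divided by the mean |null es| of the same sign.
#'
#' @param ranked A `ranked_list` from [rank_by_metric()], or a data frame
#'   with `gene` and `metric` columns already sorted non-increasing.
#' @param gene_set Character vector of genes (the signature to test).
#' @param q Metric weight exponent (default 1, metric-weighted).
#' @param R Number of random same-size gene sets (default 1000).
#' @param seed Optional integer seed.
#' @return List of class `gsea_result`: `es`, `nes`, `pval`, `peak_rank`,
#'   `running`, `n_hits`, `degenerate`.
#' @export
gsea <- function(ranked, gene_set, q = 1, R = 1000, seed = NULL) {
  stopifnot(R >= 1, q >= 0)
  genes <- ranked$gene
  metric <- ranked$metric
  N <- length(genes)
  hit <- genes %in% gene_set
  m <- sum(hit)
  if (m == 0) stop("gene set is disjoint from the ranked list")
  degenerate <- m == N
  obs <- running_es(metric, hit, q)
  if (degenerate) {
    return(structure(list(es = obs$es, nes = NA_real_, pval = NA_real_,
                          peak_rank = obs$peak, running = obs$running,
                          n_hits = m, degenerate = TRUE),
                     class = "gsea_result"))
  }
  run_nulls <- function() {
    vapply(seq_len(R), function(i) {
      h <- logical(N)
      h[sample.int(N, m)] <- TRUE
      running_es(metric, h, q)$es
    }, 0)
  }
  null_es <- if (is.null(seed)) run_nulls() else withr::with_seed(seed, run_nulls())
  same <- null_es[sign(null_es) == sign(obs$es)]
  pval <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  structure(list(es = obs$es, nes = nes, pval = pval, peak_rank = obs$peak,
                 running = obs$running, n_hits = m, degenerate = FALSE),
            class = "gsea_result")
}

# O(N) running-sum: hit increments weighted by |metric|^q, miss decrements
# uniform; returns signed extremum and its rank.
running_es <- function(metric, hit, q) {
  N <- length(hit)
  w <- abs(metric)^q
  w_hit <- w * hit
  denom <- sum(w_hit)
  if (denom == 0) { w_hit <- as.numeric(hit); denom <- sum(hit) }
  inc <- w_hit / denom
  dec <- (!hit) / (N - sum(hit))
  running <- cumsum(inc - dec)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

#' Build a ranked gene list from a metric
#'
#' Sorts genes by the metric in decreasing order; ties are broken
#' lexicographically by gene identifier so rankings are deterministic. A
#' constant metric is flagged `untestable` (the ordering then carries no
#' information).
#'
#' @param metric Named numeric vector (gene -> metric value).
#' @return A data frame of class `ranked_list` with columns `gene`, `metric`.
#' @export
rank_by_metric <- function(metric) {
  stopifnot(!is.null(names(metric)))
  metric <- metric[is.finite(metric)]
  ord <- order(-metric, names(metric))
  out <- data.frame(gene = names(metric)[ord], metric = unname(metric[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "untestable") <- length(unique(out$metric)) == 1L
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Standard ranking families for survival-network GSEA
#'
#' Produces the pre-ranked lists used to interrogate a survival module:
#' by Cox hazard ratio, by cross-tumour mutation ubiquity, by mutation
#' frequency within each single tumour type, and by mutation count within
#' each individual patient.
#'
#' @param bundle A `survnet_bundle`.
#' @param scores A `gene_score_table` (for the HR ranking); may be `NULL`.
#' @param freqs A [mutation_frequency()] matrix; may be `NULL`.
#' @param ubiquity Named ubiquity vector from [mutation_ubiquity()]; may be
#'   `NULL`.
#' @return Named list of `ranked_list` objects: `hr`, `ubiquity`,
#'   `frequency.<type>`, `patient.<id>` (whichever inputs were supplied).
#' @export
rank_builders <- function(bundle, scores = NULL, freqs = NULL,
                          ubiquity = NULL) {
  out <- list()
  if (!is.null(scores)) {
    ok <- scores$status == "ok" & is.finite(scores$hr)
    out$hr <- rank_by_metric(stats::setNames(scores$hr[ok], scores$gene[ok]))
  }
  if (!is.null(ubiquity))
    out$ubiquity <- rank_by_metric(ubiquity)
  if (!is.null(freqs))
    for (tt in colnames(freqs))
      out[[paste0("frequency.", tt)]] <-
        rank_by_metric(stats::setNames(freqs[, tt], rownames(freqs)))
  if (!is.null(bundle)) {
    counts <- unclass(bundle$mutations)
    for (p in rownames(counts))
      out[[paste0("patient.", p)]] <-
        rank_by_metric(stats::setNames(as.numeric(counts[p, ]),
                                       colnames(counts)))
  }
  out
}

#' Hypergeometric gene-set over-representation
#'
#' For each annotation term, tests whether the overlap between the gene group
#' and the term is larger than expected when drawing `|group|` genes from the
#' background urn: upper-tail hypergeometric p-value for an overlap at least
#' as large as observed, then Benjamini-Hochberg FDR across terms. Terms are
#' restricted to the background before testing.
#'
#' @param group Character vector of genes (must be contained in `background`).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector: the background universe.
#' @return Data frame of class `enrichment_table`, sorted by p-value, with
#'   columns `term`, `overlap`, `term_size`, `background_size`, `group_size`,
#'   `pval`, `fdr`, `members`.
#' @export
hypergeom_enrich <- function(group, collection, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  extra <- setdiff(group, background)
  if (length(extra))
    stop("group gene(s) outside background: ", paste(utils::head(extra, 5), collapse = ", "))
  group <- unique(group)
  N <- length(background); n <- length(group)
  rows <- lapply(names(collection), function(tm) {
    term <- intersect(collection[[tm]], background)
    K <- length(term)
    if (K == 0) return(NULL)
    ov <- intersect(group, term)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, background_size = N,
               group_size = n, pval = p,
               members = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term overlaps the background")
  out$fdr <- stats::p.adjust(out$pval, method = "BH")
  out <- out[order(out$pval, out$term),
             c("term", "overlap", "term_size", "background_size",
               "group_size", "pval", "fdr", "members")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' True-path propagation over an ontology hierarchy
#'
#' Every gene annotated to a term is added to all of the term's ancestors
#' (the true-path rule), so enrichment at a general term sees the genes of
#' its specific descendants. Idempotent; annotations are only ever added,
#' never removed. The hierarchy must be acyclic.
#'
#' @param collection Named list of gene sets.
#' @param hierarchy Data frame with columns `parent`, `child` (term ids).
#' @return The propagated collection (same names, possibly larger sets).
#' @export
propagate_ontology <- function(collection, hierarchy) {
  stopifnot(all(c("parent", "child") %in% names(hierarchy)))
  terms <- union(names(collection), unlist(hierarchy[c("parent", "child")]))
  kids <- split(hierarchy$child, hierarchy$parent)
  # Kahn topological order over parent->child edges; leftovers imply a cycle
  indeg <- stats::setNames(integer(length(terms)), terms)
  tab <- table(hierarchy$child)
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  topo <- character(0)
  while (length(queue)) {
    t0 <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, t0)
    for (ch in kids[[t0]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) < length(terms)) {
    bad <- setdiff(terms, topo)
    cyc <- hierarchy[hierarchy$parent %in% bad & hierarchy$child %in% bad, ]
    stop("cycle in ontology hierarchy at edge ",
         cyc$parent[1L], " -> ", cyc$child[1L])
  }
  sets <- stats::setNames(vector("list", length(terms)), terms)
  for (tm in terms) sets[[tm]] <- collection[[tm]]
  # children before parents: reverse topological order accumulates upward
  for (tm in rev(topo))
    for (ch in kids[[tm]])
      sets[[tm]] <- union(sets[[tm]], sets[[ch]])
  sets[lengths(sets) > 0]
}

#' Gene-age (phylostratum) enrichment
#'
#' Tests, for each ancestor in an ordered phylostratigraphy, whether the gene
#' group over-represents genes first created at that ancestor, using that
#' ancestor's gene repertoire as the urn background. Also reports the
#' cumulative fraction of group genes created at or before each ancestor.
#'
#' @param group Character vector of genes.
#' @param ages Named character vector gene -> ancestor label.
#' @param repertoires Named list ancestor -> repertoire gene vector.
#' @param strata Character vector of ancestor labels ordered oldest to
#'   youngest (defaults to `names(repertoires)`).
#' @return List: `enrichment` (an `enrichment_table` over ancestors, extra
#'   column `cumulative_fraction`), `unmapped` (group genes without an age).
#' @export
phylostratum_enrich <- function(group, ages, repertoires,
                                strata = names(repertoires)) {
  group <- unique(group)
  unmapped <- setdiff(group, names(ages))
  mapped <- setdiff(group, unmapped)
  stopifnot(all(strata %in% names(repertoires)))
  rows <- lapply(strata, function(a) {
    urn <- unique(repertoires[[a]])
    if (!length(urn)) {
      warning("empty repertoire for ancestor ", a, "; skipped")
      return(NULL)
    }
    in_urn <- intersect(mapped, urn)
    created_here <- names(ages)[ages == a]
    K <- length(intersect(created_here, urn))
    k <- length(intersect(mapped, intersect(created_here, urn)))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, length(urn) - K, length(in_urn),
                    lower.tail = FALSE)
    data.frame(term = a, overlap = k, term_size = K,
               background_size = length(urn), group_size = length(in_urn),
               pval = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no ancestor with a non-empty repertoire")
  out$fdr <- stats::p.adjust(out$pval, method = "BH")
  born <- ages[mapped]
  cum <- cumsum(vapply(strata, function(a) sum(born == a, na.rm = TRUE), 0L))
  out$cumulative_fraction <- cum[match(out$term, strata)] / max(length(mapped), 1L)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  list(enrichment = out, unmapped = unmapped)
}

#' Read a gene -> ancestor age table
#'
#' Two-column TSV (`gene`, `ancestor`) with header.
#'
#' @param path TSV path.
#' @return Named character vector gene -> ancestor.
#' @export
read_age_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("age table needs gene and ancestor columns")
  if (anyDuplicated(df[[1L]]))
    stop("gene(s) mapped to more than one ancestor: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
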