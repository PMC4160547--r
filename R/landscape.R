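#' Degree-penalised edge feature matrix
#'
#' Turns per-node information (within-module degree and per-type mutation
#' frequency) into per-edge features: for an edge between genes i and j and
#' tumour type k,
#' \deqn{e^k = \left| \frac{f_i^k}{d_i} - \frac{f_j^k}{d_j} \right|}
#' where degrees come from the module subgraph, not the full network. The
#' absolute frequency difference is penalised by node degree so hub-adjacent
#' edges contribute less.
#'
#' @param module A `module_result`.
#' @param freqs A [mutation_frequency()] matrix covering the module genes.
#' @return Numeric matrix, module edges x tumour types, rownames
#'   `"gene1|gene2"`.
#' @export
edge_transform <- function(module, freqs) {
  sub <- module$subgraph
  if (igraph::vcount(sub) < 2 || igraph::ecount(sub) == 0) {
    warning("single-node module: empty edge feature matrix")
    return(matrix(numeric(0), nrow = 0, ncol = ncol(freqs),
                  dimnames = list(NULL, colnames(freqs))))
  }
  nodes <- igraph::V(sub)$name
  missing_g <- setdiff(nodes, rownames(freqs))
  if (length(missing_g))
    stop("module gene(s) absent from frequency matrix: ",
         paste(missing_g, collapse = ", "))
  deg <- igraph::degree(sub)
  names(deg) <- nodes
  e <- igraph::ends(sub, igraph::E(sub), names = TRUE)
  feat <- t(apply(e, 1L, function(pair) {
    abs(freqs[pair[1L], ] / deg[pair[1L]] - freqs[pair[2L], ] / deg[pair[2L]])
  }))
  feat <- matrix(feat, nrow = nrow(e),
                 dimnames = list(apply(e, 1L, function(x)
                   paste(sort(x), collapse = "|")), colnames(freqs)))
  feat
}

#' Self-organising map landscape of tumour types
#'
#' Trains a rectangular-lattice SOM on tumour types as samples (feature
#' vectors = columns of the edge feature matrix) and assigns each type to its
#' best-matching cell. The codebook is initialised on the plane of the first
#' two principal components of the samples (deterministic; falls back to
#' seeded random sampling when PCA is degenerate), then trained in two
#' sequential phases — rough then fine — with a Gaussian neighbourhood whose
#' radius and learning rate decay linearly within each phase.
#'
#' @param features Edge feature matrix from [edge_transform()] (edges x
#'   types); samples are the columns.
#' @param rows,cols Grid dimensions (default 6 x 6).
#' @param epochs_rough,epochs_fine Training epochs per phase (defaults 100
#'   and 400).
#' @param alpha Initial learning rates for the two phases.
#' @param seed Integer seed controlling sample presentation order.
#' @return List of class `som_landscape`: `codebook` (cells x features),
#'   `assignment` (type -> cell index), `grid` (cell coordinates),
#'   `qe` (quantisation error at initialisation and after each phase),
#'   `degenerate` flag.
#' @export
som_landscape <- function(features, rows = 6, cols = 6,
                          epochs_rough = 100, epochs_fine = 400,
                          alpha = c(0.5, 0.05), seed = 1) {
  X <- t(features)  # samples (tumour types) in rows
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("need at least 2 tumour types")
  if (rows * cols < 2) stop("grid must have at least 2 cells")
  grid <- as.matrix(expand.grid(row = seq_len(rows), col = seq_len(cols)))
  ncell <- nrow(grid)
  degenerate <- all(apply(X, 2L, function(col) length(unique(col)) == 1L))

  # codebook init: span of the first two principal components
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  pc <- tryCatch(stats::prcomp(Xc, center = FALSE), error = function(e) NULL)
  if (!is.null(pc) && ncol(pc$rotation) >= 1 && pc$sdev[1L] > 0) {
    u1 <- seq(-1, 1, length.out = rows) * pc$sdev[1L]
    v2 <- if (length(pc$sdev) >= 2 && pc$sdev[2L] > 0)
      seq(-1, 1, length.out = cols) * pc$sdev[2L] else rep(0, cols)
    dir1 <- pc$rotation[, 1L]
    dir2 <- if (ncol(pc$rotation) >= 2) pc$rotation[, 2L] else rep(0, d)
    codebook <- t(vapply(seq_len(ncell), function(i) {
      ctr + u1[grid[i, 1L]] * dir1 + v2[grid[i, 2L]] * dir2
    }, numeric(d)))
  } else {
    codebook <- withr::with_seed(seed, X[sample.int(n, ncell, replace = TRUE), , drop = FALSE])
  }

  grid_d2 <- as.matrix(stats::dist(grid))^2
  qe <- c(init = quantisation_error(X, codebook))
  radius0 <- sqrt((rows - 1)^2 + (cols - 1)^2) / 2

  train_phase <- function(codebook, epochs, alpha0, r_start, r_end, phase_seed) {
    withr::with_seed(phase_seed, {
      for (ep in seq_len(epochs)) {
        frac <- (ep - 1) / max(epochs - 1, 1)
        a <- alpha0 * (1 - frac) + 1e-4 * frac
        r <- r_start * (1 - frac) + r_end * frac
        for (i in sample.int(n)) {
          x <- X[i, ]
          bmu <- which.min(colSums((t(codebook) - x)^2))
          h <- exp(-grid_d2[bmu, ] / (2 * r^2))
          codebook <- codebook + a * h * sweep(-codebook, 2L, x, `+`)
        }
      }
      codebook
    })
  }
  codebook <- train_phase(codebook, epochs_rough, alpha[1L],
                          radius0, max(radius0 / 4, 1), seed)
  qe["rough"] <- quantisation_error(X, codebook)
  codebook <- train_phase(codebook, epochs_fine, alpha[2L],
                          max(radius0 / 4, 1), 0.1, seed + 1L)
  qe["fine"] <- quantisation_error(X, codebook)

  assignment <- apply(X, 1L, function(x)
    which.min(colSums((t(codebook) - x)^2)))
  names(assignment) <- rownames(X)
  structure(list(codebook = codebook, assignment = assignment, grid = grid,
                 qe = qe, degenerate = degenerate,
                 meta = list(rows = rows, cols = cols, seed = seed,
                             epochs = c(epochs_rough, epochs_fine))),
            class = "som_landscape")
}

quantisation_error <- function(X, codebook) {
  mean(apply(X, 1L, function(x)
    sqrt(min(colSums((t(codebook) - x)^2)))))
}

#' @export
print.som_landscape <- function(x, ...) {
  cat("SOM landscape:", x$meta$rows, "x", x$meta$cols, "grid;",
      length(x$assignment), "samples; quantisation error",
      format(x$qe[length(x$qe)], digits = 4), "\n")
  invisible(x)
}

#' Bootstrap neighbour-joining tree over tumour types
#'
#' Builds a Saitou-Nei neighbour-joining tree from Euclidean distances
#' between the tumour-type columns of a module-restricted mutation-frequency
#' matrix, then bootstraps by resampling genes (rows) with replacement and
#' recording, for each internal bipartition, the fraction of replicate trees
#' containing it.
#'
#' @param freqs Frequency matrix (module genes x tumour types).
#' @param boot_reps Bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @return List of class `support_tree`: `tree` (an `ape::phylo` with
#'   bipartition supports in `node.label`), `support` (numeric in \[0, 1\]),
#'   `newick` (serialised tree).
#' @export
nj_tree <- function(freqs, boot_reps = 100, seed = 1) {
  types <- colnames(freqs)
  k <- length(types)
  if (k < 2) stop("need at least 2 tumour types")
  X <- t(freqs)  # taxa in rows, genes in columns
  if (k == 2) {
    tree <- ape::read.tree(
      text = paste0("(", types[1L], ":1,", types[2L], ":1);"))
    return(structure(list(tree = tree, support = 1,
                          newick = ape::write.tree(tree)),
                     class = "support_tree"))
  }
  build <- function(xx) ape::nj(stats::dist(xx))
  tree <- build(X)
  boots <- withr::with_seed(seed, {
    lapply(seq_len(boot_reps), function(b) {
      idx <- sample.int(ncol(X), replace = TRUE)
      build(X[, idx, drop = FALSE])
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / boot_reps
  tree$node.label <- format(support, trim = TRUE)
  structure(list(tree = tree, support = support,
                 newick = ape::write.tree(tree)),
            class = "support_tree")
}

#' @export
print.support_tree <- function(x, ...) {
  cat("NJ tree:", length(x$tree$tip.label), "tumour types;",
      "mean bipartition support",
      format(mean(x$support), digits = 3), "\n")
  cat(x$newick, "\n")
  invisible(x)
}
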