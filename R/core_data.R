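#' Read a patient-by-gene mutation count matrix
#'
#' The expected layout is a tab-delimited file with a header row of gene
#' identifiers, a first column of patient identifiers, and a body of
#' non-negative integer somatic mutation counts (a non-zero entry is the
#' number of mutations observed in that gene for that patient).
#'
#' @param path Path to a TSV file.
#' @return An integer matrix with patients as rows and genes as columns,
#'   of class `mutation_matrix`.
#' @export
read_mutation_matrix <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("mutation matrix needs a patient column plus at least one gene column")
  patients <- as.character(df[[1L]])
  body <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(body) <- "double"
  if (anyNA(body)) stop("mutation matrix contains missing or non-numeric cells")
  rownames(body) <- patients
  as_mutation_matrix(body)
}

#' Construct and validate a mutation matrix
#'
#' @param counts Numeric matrix, patients in rows, genes in columns; rownames
#'   and colnames are the patient and gene identifiers.
#' @return The validated integer matrix with class `mutation_matrix`.
#' @export
as_mutation_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("mutation matrix requires patient rownames and gene colnames")
  dup_p <- unique(rownames(counts)[duplicated(rownames(counts))])
  dup_g <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_p)) stop("duplicate patient identifiers: ", paste(dup_p, collapse = ", "))
  if (length(dup_g)) stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  if (any(counts < 0)) stop("negative count in mutation matrix")
  if (any(counts != round(counts))) stop("non-integer count in mutation matrix")
  storage.mode(counts) <- "integer"
  class(counts) <- c("mutation_matrix", class(counts))
  counts
}

#' Write a mutation matrix as TSV
#'
#' @param mm A `mutation_matrix`.
#' @param path Output file path.
#' @export
write_mutation_matrix <- function(mm, path) {
  df <- data.frame(patient = rownames(mm), as.data.frame(unclass(mm)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Required columns (matched by name, any order): `patient`, `time` (survival
#' time in days, > 0), `event` (1 = death observed, 0 = right-censored),
#' `age` (years), `gender`, `tumour_type`. Unknown gender or tumour labels are
#' preserved verbatim as factor levels.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` of class `clinical_table`, one row per patient.
#' @export
read_clinical <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_clinical(df)
}

#' Construct and validate a clinical table
#'
#' @param df A data frame with columns patient, time, event, age, gender,
#'   tumour_type.
#' @return A validated `clinical_table`.
#' @export
as_clinical <- function(df) {
  need <- c("patient", "time", "event", "age", "gender", "tumour_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("clinical table is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, need]
  df$patient <- as.character(df$patient)
  if (anyDuplicated(df$patient))
    stop("duplicate patient identifiers in clinical table: ",
         paste(unique(df$patient[duplicated(df$patient)]), collapse = ", "))
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)
  df$age <- as.numeric(df$age)
  if (anyNA(df$time) || any(df$time <= 0)) stop("survival time must be > 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  df$gender <- factor(as.character(df$gender))
  df$tumour_type <- factor(as.character(df$tumour_type))
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table as TSV
#'
#' @param clin A `clinical_table`.
#' @param path Output file path.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(as.data.frame(clin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an undirected gene interaction network
#'
#' Accepts a two-column tab-delimited edge list (with or without a header) or
#' a GraphML file. The result is a simple undirected graph: duplicate edges
#' are collapsed, self-loops dropped, and isolated nodes removed (an isolated
#' gene can never join a connected module).
#'
#' @param path Path to the network file.
#' @param format `"auto"` (by extension), `"tsv"` or `"graphml"`.
#' @return An `igraph` object with gene identifiers as vertex names.
#' @export
read_network <- function(path, format = c("auto", "tsv", "graphml")) {
  stopifnot(file.exists(path))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (is.null(igraph::V(g)$name)) {
      ids <- igraph::vertex_attr(g, "id")
      igraph::V(g)$name <- if (!is.null(ids)) ids else as.character(seq_len(igraph::vcount(g)))
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty network file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
      stop("edge list line without two columns at line ",
           which(lengths(parts) < 2L)[1L])
    ed <- do.call(rbind, lapply(parts, function(x) x[1:2]))
    # tolerate a header row such as "gene1\tgene2"
    if (tolower(ed[1, 1]) %in% c("gene1", "from", "source", "node1"))
      ed <- ed[-1L, , drop = FALSE]
    if (!nrow(ed)) stop("network file contains no edges")
    g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  }
  as_gene_graph(g)
}

#' Canonicalise a gene graph
#'
#' Makes a graph simple and undirected, drops self-loops and isolated
#' vertices, and sorts vertices lexicographically so that downstream
#' deterministic tie-breaking is reproducible across input orderings.
#'
#' @param g An `igraph` object with named vertices.
#' @return A simple undirected `igraph`.
#' @export
as_gene_graph <- function(g) {
  if (is.null(igraph::V(g)$name)) stop("gene graph requires named vertices")
  g <- igraph::as_undirected(g, mode = "collapse")
  n_loops <- sum(igraph::which_loop(g))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (n_loops > 0)
    message(n_loops, " self-loop(s) dropped from network")
  iso <- which(igraph::degree(g) == 0)
  if (length(iso)) g <- igraph::delete_vertices(g, iso)
  if (igraph::vcount(g) == 0) stop("network has no non-isolated nodes")
  perm <- match(sort(igraph::V(g)$name), igraph::V(g)$name)
  igraph::permute(g, order(perm))
}

#' Write a network to GraphML
#'
#' @param g An `igraph` object.
#' @param path Output path.
#' @export
write_network <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Harmonise mutation, clinical and network inputs into one analysis bundle
#'
#' Patients are restricted to the intersection of the mutation matrix and the
#' clinical table (mirroring the retention of only patients with survival
#' information), with identical ordering in both. Genes are kept in the matrix
#' even when absent from the graph; restriction to the network happens at
#' module search.
#'
#' @param mm A `mutation_matrix`.
#' @param clin A `clinical_table`.
#' @param graph An `igraph` gene network.
#' @return A list of class `survnet_bundle` with elements `mutations`,
#'   `clinical`, `graph`.
#' @export
harmonise <- function(mm, clin, graph) {
  common <- intersect(rownames(mm), clin$patient)
  if (!length(common)) stop("no patients shared between mutation matrix and clinical table")
  dropped_mm <- nrow(mm) - length(common)
  dropped_cl <- nrow(clin) - length(common)
  if (dropped_mm > 0 || dropped_cl > 0)
    message("harmonise: dropped ", dropped_mm, " matrix-only and ",
            dropped_cl, " clinical-only patient(s)")
  common <- sort(common)
  mm2 <- unclass(mm)[common, , drop = FALSE]
  class(mm2) <- c("mutation_matrix", class(mm2))
  clin2 <- clin[match(common, clin$patient), , drop = FALSE]
  rownames(clin2) <- NULL
  clin2$tumour_type <- droplevels(clin2$tumour_type)
  clin2$gender <- droplevels(clin2$gender)
  out <- list(mutations = mm2, clinical = clin2, graph = graph)
  class(out) <- "survnet_bundle"
  out
}

#' @export
print.survnet_bundle <- function(x, ...) {
  cat("survnet bundle:", nrow(x$mutations), "patients x",
      ncol(x$mutations), "genes;",
      igraph::vcount(x$graph), "network nodes /",
      igraph::ecount(x$graph), "edges;",
      nlevels(x$clinical$tumour_type), "tumour type(s)\n")
  invisible(x)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-delimited `name`, `description`,
#' then member genes.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("GMT line ", bad[1L], " has fewer than 3 fields")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
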