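#' Run the full survival-network workflow
#'
#' Executes the stages in order — score, module, robustness, randomise,
#' landscape, njtree, gsea, enrich, ages — skipping any stage disabled in the
#' configuration, and writes every stage output plus a JSON run manifest
#' (tool version, config snapshot, input digests, seeds, per-stage wall-clock
#' and output paths) into `out_dir`.
#'
#' @param config A configuration list, or a path to a YAML/JSON file holding
#'   one. Recognised top-level fields: `inputs` (`mutations`, `clinical`,
#'   `network` file paths), `out_dir`, `seed`, and per-stage blocks `score`
#'   (`min_mutated`), `module` (`pcut` or `size`, `tol`), `robustness`
#'   (`enabled`), `randomise` (`enabled`, `reps`, `n_bins`), `landscape`
#'   (`enabled`, `rows`, `cols`), `njtree` (`enabled`, `boot`), `gsea`
#'   (`enabled`, `reps`, `gmt`), `enrich` (`enabled`, `gmt`), `ages`
#'   (`enabled`, `table`, `repertoires`).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  seed <- cfg$seed %||% 1L
  manifest <- list(
    tool = paste("survnet", as.character(utils::packageVersion("survnet"))),
    config = cfg, seeds = list(master = seed),
    inputs = lapply(cfg$inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = list(), outputs = list())

  tic <- function() proc.time()[["elapsed"]]
  note <- function(stage, t0, paths) {
    manifest$stages[[stage]] <<- list(seconds = round(tic() - t0, 3))
    manifest$outputs[[stage]] <<- paths
  }
  enabled <- function(stage)
    !isFALSE((cfg[[stage]] %||% list())$enabled %||% TRUE)
  out_path <- function(...) file.path(cfg$out_dir, ...)

  run_stage <- function(stage, fn) {
    t0 <- tic()
    paths <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    note(stage, t0, paths)
  }

  # -- load & harmonise ------------------------------------------------
  mm <- read_mutation_matrix(cfg$inputs$mutations)
  clin <- read_clinical(cfg$inputs$clinical)
  graph <- read_network(cfg$inputs$network)
  bundle <- harmonise(mm, clin, graph)

  scores <- NULL; module <- NULL; freqs <- NULL

  run_stage("score", function() {
    scores <<- cox_lrt_per_gene(
      bundle, min_mutated = (cfg$score %||% list())$min_mutated %||% 2)
    p <- out_path("scores.tsv")
    utils::write.table(scores, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  })

  run_stage("module", function() {
    mcfg <- cfg$module %||% list()
    module <<- if (!is.null(mcfg$size)) {
      search_fixed_size(scores, graph, mcfg$size, tol = mcfg$tol %||% 2)
    } else {
      max_scoring_subgraph(score_nodes(scores, graph, mcfg$pcut %||% 0.05))
    }
    sub <- module$subgraph
    p <- out_path("module.graphml")
    write_network(sub, p)
    p2 <- out_path("module_nodes.tsv")
    utils::write.table(module$nodes, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(p, p2)
  })

  freqs <- mutation_frequency(bundle)

  if (enabled("robustness") && nlevels(bundle$clinical$tumour_type) >= 2)
    run_stage("robustness", function() {
      conf <- loo_edge_confidence(bundle, module)
      p <- out_path("edge_confidence.tsv")
      utils::write.table(conf, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    })

  if (enabled("randomise"))
    run_stage("randomise", function() {
      rcfg <- cfg$randomise %||% list()
      es <- edge_significance(bundle, scores, module,
                              R = rcfg$reps %||% 100,
                              n_bins = rcfg$n_bins %||% 10, seed = seed)
      p <- out_path("edge_significance.tsv")
      utils::write.table(es$edges, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines(paste("aggregated_pval", format(es$aggregated_pval)),
                 out_path("aggregated_pval.txt"))
      c(p, out_path("aggregated_pval.txt"))
    })

  if (enabled("landscape"))
    run_stage("landscape", function() {
      lcfg <- cfg$landscape %||% list()
      feats <- edge_transform(module, freqs)
      som <- som_landscape(feats, rows = lcfg$rows %||% 6,
                           cols = lcfg$cols %||% 6, seed = seed)
      p <- out_path("landscape_assignment.tsv")
      utils::write.table(
        data.frame(tumour_type = names(som$assignment),
                   cell = unname(som$assignment),
                   row = som$grid[som$assignment, 1L],
                   col = som$grid[som$assignment, 2L]),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      p2 <- out_path("landscape_codebook.tsv")
      utils::write.table(som$codebook, p2, sep = "\t", quote = FALSE)
      c(p, p2)
    })

  if (enabled("njtree") && nlevels(bundle$clinical$tumour_type) >= 3)
    run_stage("njtree", function() {
      ncfg <- cfg$njtree %||% list()
      mod_genes <- intersect(rownames(freqs), module$nodes$gene)
      tr <- nj_tree(freqs[mod_genes, , drop = FALSE],
                    boot_reps = ncfg$boot %||% 100, seed = seed)
      p <- out_path("njtree.nwk")
      writeLines(tr$newick, p)
      p
    })

  if (enabled("gsea"))
    run_stage("gsea", function() {
      gcfg <- cfg$gsea %||% list()
      ub <- mutation_ubiquity(freqs)
      ranked <- rank_builders(NULL, scores = scores, freqs = freqs,
                              ubiquity = ub)
      sig <- module$nodes$gene
      rows <- lapply(names(ranked), function(nm) {
        r <- ranked[[nm]]
        if (!any(r$gene %in% sig)) return(NULL)
        g <- gsea(r, sig, R = gcfg$reps %||% 1000, seed = seed)
        data.frame(ranking = nm, es = g$es, nes = g$nes, pval = g$pval,
                   peak_rank = g$peak_rank, stringsAsFactors = FALSE)
      })
      p <- out_path("gsea.tsv")
      utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    })

  if (enabled("enrich") && !is.null((cfg$enrich %||% list())$gmt))
    run_stage("enrich", function() {
      sets <- read_gmt(cfg$enrich$gmt)
      tab <- hypergeom_enrich(module$nodes$gene, sets,
                              background = colnames(bundle$mutations))
      p <- out_path("enrichment.tsv")
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    })

  if (enabled("ages") && !is.null((cfg$ages %||% list())$table))
    run_stage("ages", function() {
      ages <- read_age_table(cfg$ages$table)
      reps <- read_gmt(cfg$ages$repertoires)
      res <- phylostratum_enrich(module$nodes$gene, ages, reps)
      p <- out_path("age_enrichment.tsv")
      utils::write.table(res$enrichment, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    })

  # manifest last, once all artifacts exist
  manifest$outputs <- lapply(manifest$outputs, function(paths)
    lapply(paths, function(p) list(path = p, md5 = unname(tools::md5sum(p)))))
  mpath <- out_path("manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(manifest)
}

load_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), file.exists(config))
  if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON instead")
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
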