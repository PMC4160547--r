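#' Configuration for a synthetic survival cohort
#'
#' The generated world emulates pan-cancer mutation/survival cohorts: sparse
#' integer somatic mutation counts, right-censored exponential survival with
#' proportional hazards (so the Cox model is correctly specified and
#' parameter-recovery tests are meaningful), clinical covariates, and a
#' planted survival-associated connected module on a scale-free network.
#'
#' @param n_patients Cohort size (default 600).
#' @param n_genes Number of genes (default 500).
#' @param tumour_types Named numeric vector of type proportions summing to 1
#'   (default 4 types at 0.4/0.3/0.2/0.1, exercising leave-one-type-out
#'   asymmetry).
#' @param network Network model: `"ba"` (Barabasi-Albert preferential
#'   attachment) or `"er"` (Erdos-Renyi).
#' @param ba_m Edges per new node for the BA model (default 2).
#' @param er_p Edge probability for the ER model.
#' @param module_size Planted connected module size (default 15).
#' @param beta Log-hazard increase per mutation in a module gene (default 1).
#' @param lambda_mod Poisson mutation rate for module genes (default 0.3).
#' @param lambda_bg Poisson mutation rate for background genes (default 0.05).
#' @param censoring Target fraction of censored patients (default 0.3).
#' @param age_effect Log-hazard per year of age above 60 (default 0.01).
#' @param gender_effect Log-hazard for male vs female (default 0.1).
#' @param type_effects Per-type baseline log-hazards (default small spread).
#' @param baseline_hazard Baseline hazard per day (default 1/1000).
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 600, n_genes = 500,
                       tumour_types = c(T1 = 0.4, T2 = 0.3, T3 = 0.2, T4 = 0.1),
                       network = c("ba", "er"), ba_m = 2, er_p = 0.01,
                       module_size = 15, beta = 1,
                       lambda_mod = 0.3, lambda_bg = 0.05,
                       censoring = 0.3, age_effect = 0.01,
                       gender_effect = 0.1,
                       type_effects = NULL, baseline_hazard = 1e-3,
                       seed = 1) {
  network <- match.arg(network)
  stopifnot(n_patients >= 2, n_genes >= 2, module_size >= 1,
            module_size <= n_genes, lambda_mod >= 0, lambda_bg >= 0,
            censoring >= 0, censoring < 1, baseline_hazard > 0)
  if (abs(sum(tumour_types) - 1) > 1e-8)
    stop("tumour type proportions must sum to 1")
  if (is.null(type_effects))
    type_effects <- stats::setNames(
      seq(0, 0.2, length.out = length(tumour_types)), names(tumour_types))
  structure(list(n_patients = n_patients, n_genes = n_genes,
                 tumour_types = tumour_types, network = network,
                 ba_m = ba_m, er_p = er_p, module_size = module_size,
                 beta = beta, lambda_mod = lambda_mod, lambda_bg = lambda_bg,
                 censoring = censoring, age_effect = age_effect,
                 gender_effect = gender_effect, type_effects = type_effects,
                 baseline_hazard = baseline_hazard, seed = seed),
            class = "sim_config")
}

#' Simulate a cohort with a planted survival-associated module
#'
#' Generates (1) a gene network; (2) a connected planted module chosen by
#' seeded breadth-first growth from a random start; (3) per-patient Poisson
#' mutation counts, rate `lambda_mod` for module genes and `lambda_bg`
#' otherwise; (4) exponential survival times with hazard
#' `h0 * exp(beta * module mutations + covariate effects)` where age ~
#' N(60, 10), gender ~ Bernoulli(0.5) and tumour type follows the configured
#' proportions with type-specific baseline log-hazards; (5) independent
#' exponential censoring calibrated to the configured censoring fraction.
#' The same seed yields a byte-identical cohort.
#'
#' @param cfg A `sim_config`.
#' @return A list of class `simulated_cohort`: `bundle` (a
#'   `survnet_bundle`), `planted_genes`, `planted_edges` (2-column matrix),
#'   `beta`, `true_hazard`, `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    g <- switch(cfg$network,
      ba = igraph::sample_pa(cfg$n_genes, m = cfg$ba_m, directed = FALSE),
      er = igraph::sample_gnp(cfg$n_genes, cfg$er_p))
    igraph::V(g)$name <- sprintf("G%04d", seq_len(cfg$n_genes))
    g <- as_gene_graph(g)

    planted <- plant_module(g, cfg$module_size)

    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    rate <- ifelse(genes %in% planted, cfg$lambda_mod, cfg$lambda_bg)
    counts <- matrix(stats::rpois(cfg$n_patients * cfg$n_genes,
                                  rep(rate, each = cfg$n_patients)),
                     nrow = cfg$n_patients,
                     dimnames = list(sprintf("P%04d", seq_len(cfg$n_patients)),
                                     genes))

    age <- round(stats::rnorm(cfg$n_patients, 60, 10), 1)
    gender <- sample(c("female", "male"), cfg$n_patients, replace = TRUE)
    tt <- sample(names(cfg$tumour_types), cfg$n_patients, replace = TRUE,
                 prob = cfg$tumour_types)
    mod_burden <- rowSums(counts[, planted, drop = FALSE])
    log_h <- log(cfg$baseline_hazard) + cfg$beta * mod_burden +
      cfg$age_effect * (age - 60) +
      cfg$gender_effect * (gender == "male") +
      cfg$type_effects[tt]
    h <- exp(log_h)
    t_event <- stats::rexp(cfg$n_patients, rate = h)
    if (cfg$censoring > 0) {
      # median, not mean: exp(beta * burden) makes the mean hazard explode
      # on a few high-burden patients and would censor everyone
      cens_rate <- stats::median(h) * cfg$censoring / (1 - cfg$censoring)
      t_cens <- stats::rexp(cfg$n_patients, rate = cens_rate)
    } else t_cens <- rep(Inf, cfg$n_patients)
    # tiny floor only guards exact zeros; a larger one would tie the event
    # times of high-burden patients together
    time <- pmax(pmin(t_event, t_cens), 1e-12)
    event <- as.numeric(t_event <= t_cens)

    clin <- as_clinical(data.frame(
      patient = rownames(counts), time = time, event = event, age = age,
      gender = gender, tumour_type = tt, stringsAsFactors = FALSE))
    bundle <- harmonise(as_mutation_matrix(counts), clin, g)
    sub <- igraph::induced_subgraph(g, planted)
    structure(list(bundle = bundle, planted_genes = planted,
                   planted_edges = igraph::ends(sub, igraph::E(sub),
                                                names = TRUE),
                   beta = cfg$beta, true_hazard = h, config = cfg),
              class = "simulated_cohort")
  })
}

# seeded BFS growth of a connected module; retries from new starts when a
# component is too small, errors after 10 attempts
plant_module <- function(g, size) {
  nodes <- igraph::V(g)$name
  if (size > igraph::vcount(g)) stop("module_size exceeds network size")
  for (try in seq_len(10)) {
    start <- sample(nodes, 1L)
    bfs <- igraph::bfs(g, root = start, order = TRUE,
                       unreachable = FALSE)$order
    bfs <- bfs[!is.na(bfs)]
    if (length(bfs) >= size)
      return(sort(igraph::V(g)$name[as.integer(bfs[seq_len(size)])]))
  }
  stop("could not grow a connected module of size ", size,
       " after 10 attempts (graph too fragmented)")
}

#' End-to-end planted-module recovery harness
#'
#' Runs Cox scoring and fixed-size module search on a simulated cohort and
#' compares the recovered node set against the planted one.
#'
#' @param cohort A `simulated_cohort`.
#' @param target_size Module size to request (defaults to the planted size).
#' @param min_mutated Passed to [cox_lrt_per_gene()].
#' @return List: `precision`, `recall`, `f1`, `recovered` (gene vector),
#'   `module` (the `module_result`).
#' @export
recovery_harness <- function(cohort, target_size = NULL, min_mutated = 2) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (is.null(target_size)) target_size <- length(cohort$planted_genes)
  scores <- cox_lrt_per_gene(cohort$bundle, min_mutated = min_mutated)
  mod <- search_fixed_size(scores, cohort$bundle$graph, target_size)
  got <- igraph::V(mod$subgraph)$name
  tp <- length(intersect(got, cohort$planted_genes))
  precision <- if (length(got)) tp / length(got) else 0
  recall <- tp / length(cohort$planted_genes)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       recovered = got, module = mod)
}

#' Write a simulated cohort to standard on-disk formats
#'
#' Emits the mutation matrix, clinical table (TSV), network (GraphML) and a
#' `truth.json` with the planted genes, effect size and seed.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    mutations = file.path(dir, "mutations.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    network = file.path(dir, "network.graphml"),
    truth = file.path(dir, "truth.json"))
  write_mutation_matrix(cohort$bundle$mutations, paths["mutations"])
  write_clinical(cohort$bundle$clinical, paths["clinical"])
  write_network(cohort$bundle$graph, paths["network"])
  jsonlite::write_json(
    list(planted_genes = cohort$planted_genes, beta = cohort$beta,
         seed = cohort$config$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
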