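#' Per-gene Cox proportional-hazards likelihood-ratio scoring
#'
#' For each gene mutated in at least `min_mutated` patients, fits a baseline
#' Cox model `Surv(time, event) ~ age + gender + tumour_type` and a full model
#' that adds the gene's integer mutation-count vector, and compares them by a
#' likelihood-ratio test: `lrt_stat = 2 * (loglik_full - loglik_base)`,
#' p-value from the upper tail of a chi-squared distribution with 1 degree of
#' freedom, hazard ratio `exp(beta_gene)`. Ties are handled with the Efron
#' approximation. Covariates with no variation in the cohort are dropped from
#' the baseline with a warning. Genes whose fit fails carry an explicit
#' `status` flag rather than fabricated values.
#'
#' @param bundle A `survnet_bundle` from [harmonise()].
#' @param min_mutated Minimum number of patients with at least one mutation
#'   for a gene to be fitted (default 2); below it the gene is flagged
#'   `"skipped"`.
#' @param binarise If `TRUE`, the explanatory variable is mutated yes/no
#'   rather than the raw mutation count. Default `FALSE`: counts enter the
#'   model untransformed.
#' @return A data frame of class `gene_score_table` with columns `gene`,
#'   `hr`, `pval`, `lrt_stat`, `n_mutated`, `status`.
#' @export
cox_lrt_per_gene <- function(bundle, min_mutated = 2, binarise = FALSE) {
  stopifnot(inherits(bundle, "survnet_bundle"), min_mutated >= 0)
  clin <- bundle$clinical
  if (length(unique(clin$time[clin$event == 1])) < 2)
    stop("need at least 2 distinct event times for Cox regression")
  base <- baseline_cox(clin)
  counts <- unclass(bundle$mutations)
  genes <- colnames(counts)
  n_mut <- colSums(counts >= 1L)
  out <- data.frame(gene = genes, hr = NA_real_, pval = NA_real_,
                    lrt_stat = NA_real_, n_mutated = as.integer(n_mut),
                    status = "ok", stringsAsFactors = FALSE)
  for (j in seq_along(genes)) {
    if (n_mut[j] < min_mutated || n_mut[j] == 0L) {
      out$status[j] <- "skipped"
      next
    }
    x <- as.numeric(counts[, j])
    if (binarise) x <- as.numeric(x >= 1)
    fit <- fit_gene_cox(base, x)
    if (is.null(fit)) {
      out$status[j] <- "failed"
    } else {
      out$hr[j] <- fit["hr"]
      out$pval[j] <- fit["pval"]
      out$lrt_stat[j] <- fit["lrt"]
    }
  }
  class(out) <- c("gene_score_table", "data.frame")
  out
}

# Baseline Cox fit on the clinical covariates only; zero-variance covariates
# are dropped so degenerate cohorts (single tumour type, single gender) still
# fit. Returns the fitted model plus the design pieces reused per gene.
baseline_cox <- function(clin) {
  terms <- character(0)
  if (length(unique(clin$age)) > 1) terms <- c(terms, "age")
  if (nlevels(droplevels(clin$gender)) > 1) terms <- c(terms, "gender")
  if (nlevels(droplevels(clin$tumour_type)) > 1) terms <- c(terms, "tumour_type")
  dropped <- setdiff(c("age", "gender", "tumour_type"), terms)
  if (length(dropped))
    warning("zero-variance covariate(s) dropped from baseline: ",
            paste(dropped, collapse = ", "))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = clin, ties = "efron")
  loglik_base <- if (length(terms)) fit$loglik[2L] else fit$loglik[1L]
  list(clin = clin, rhs = rhs, has_covars = length(terms) > 0,
       loglik = loglik_base)
}

# Full model = baseline covariates + the gene term; returns c(hr, pval, lrt)
# or NULL on failure/non-convergence.
fit_gene_cox <- function(base, x) {
  dat <- base$clin
  dat$..gene <- x
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 base$rhs, "+ ..gene"))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = dat, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  beta <- fit$coefficients["..gene"]
  if (!is.finite(beta)) return(NULL)
  lrt <- 2 * (fit$loglik[2L] - base$loglik)
  # numerical jitter can make a nested LRT microscopically negative
  lrt <- max(lrt, 0)
  c(hr = unname(exp(beta)),
    pval = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    lrt = lrt)
}

#' Cox statistics for sequential gene combinations
#'
#' Orders the given genes by ascending single-gene LRT p-value (the most
#' significant first) and, for each prefix of length k, fits the same
#' covariate-adjusted Cox LRT with an aggregated explanatory variable: the
#' per-patient sum of mutation counts over the k combined genes.
#'
#' @param bundle A `survnet_bundle`.
#' @param scores A `gene_score_table` from [cox_lrt_per_gene()].
#' @param genes Character vector of genes to combine (must be in the matrix).
#' @return A data frame of class `combination_curve` with columns `k`,
#'   `gene_added`, `hr`, `pval`, `lrt_stat`, `status`.
#' @export
cox_combination <- function(bundle, scores, genes) {
  stopifnot(inherits(bundle, "survnet_bundle"))
  if (!length(genes)) stop("empty gene list")
  missing_g <- setdiff(genes, colnames(bundle$mutations))
  if (length(missing_g))
    stop("gene(s) absent from mutation matrix: ", paste(missing_g, collapse = ", "))
  pv <- scores$pval[match(genes, scores$gene)]
  ord <- order(pv, genes)  # ties broken by gene id for determinism
  genes <- genes[ord]
  base <- baseline_cox(bundle$clinical)
  counts <- unclass(bundle$mutations)
  agg <- rep(0, nrow(counts))
  out <- data.frame(k = seq_along(genes), gene_added = genes, hr = NA_real_,
                    pval = NA_real_, lrt_stat = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  for (k in seq_along(genes)) {
    agg <- agg + as.numeric(counts[, genes[k]])
    fit <- fit_gene_cox(base, agg)
    if (is.null(fit)) out$status[k] <- "failed"
    else {
      out$hr[k] <- fit["hr"]; out$pval[k] <- fit["pval"]
      out$lrt_stat[k] <- fit["lrt"]
    }
  }
  class(out) <- c("combination_curve", "data.frame")
  out
}

#' Within-tumour-type mutation frequency
#'
#' For gene i and tumour type k, the frequency `f_i^k` is the proportion of
#' type-k patients carrying at least one mutation in gene i.
#'
#' @param bundle A `survnet_bundle`.
#' @return A numeric matrix genes x tumour types with entries in \[0, 1\];
#'   attribute `n_patients` holds the per-type patient counts.
#' @export
mutation_frequency <- function(bundle) {
  stopifnot(inherits(bundle, "survnet_bundle"))
  types <- levels(bundle$clinical$tumour_type)
  counts <- unclass(bundle$mutations) >= 1L
  f <- sapply(types, function(tt) {
    idx <- bundle$clinical$tumour_type == tt
    colMeans(counts[idx, , drop = FALSE])
  })
  f <- matrix(f, nrow = ncol(counts), dimnames = list(colnames(counts), types))
  attr(f, "n_patients") <- table(bundle$clinical$tumour_type)[types]
  f
}

#' Cross-tumour mutation ubiquity
#'
#' Quantifies how evenly a gene's mutation frequency spreads across tumour
#' types:
#' \deqn{u = \left(\frac{\sum_i f_i}{\sqrt{\sum_i f_i^2}} - 1\right) /
#'       (\sqrt{n} - 1)}
#' where `n` is the number of tumour types. `u` is 0 when only a single type
#' is mutated and exactly 1 when all types share an identical non-zero
#' frequency; it is invariant to positive rescaling of the frequencies and to
#' permutation of the types. An all-zero frequency vector returns 0 by
#' convention, flagged via the `"all_zero"` attribute.
#'
#' @param f Numeric vector of per-type frequencies in \[0, 1\] (a single
#'   gene's row of [mutation_frequency()]), or a matrix with genes in rows.
#' @return A single ubiquity value, or a named vector for matrix input.
#' @export
mutation_ubiquity <- function(f) {
  if (is.matrix(f)) {
    u <- apply(f, 1L, mutation_ubiquity)
    return(u)
  }
  f <- as.numeric(f)
  n <- length(f)
  if (n < 2) stop("mutation ubiquity needs at least 2 tumour types")
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  s1 <- sum(f)
  s2 <- sqrt(sum(f^2))
  if (s2 == 0) {
    u <- 0
    attr(u, "all_zero") <- TRUE
    return(u)
  }
  (s1 / s2 - 1) / (sqrt(n) - 1)
}
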