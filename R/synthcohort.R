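#' Default module archetype matrix
#'
#' Builds the 3 x n_modules matrix of module-level mean shifts (log2 units)
#' that defines the three latent clusters. A fraction of the modules is
#' informative; informative modules cycle through six single-cluster shift
#' patterns (+shift or -shift in exactly one cluster), the rest carry no
#' cluster signal and exist so downstream feature selection has something to
#' discard.
#'
#' @param n_modules number of co-regulated gene modules.
#' @param informative_fraction fraction of modules with a cluster shift.
#' @param shift shift magnitude in log2 units.
#' @return A 3 x `n_modules` numeric matrix.
#' @export
default_archetypes <- function(n_modules, informative_fraction = 0.3, shift = 2) {
  A <- matrix(0, nrow = 3, ncol = n_modules)
  n_inf <- round(informative_fraction * n_modules)
  if (n_inf == 0) return(A)
  patterns <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                    c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  for (m in seq_len(n_inf))
    A[, m] <- shift * patterns[(m - 1) %% 6 + 1, ]
  A
}

#' Configuration for the multi-cohort simulator
#'
#' The defaults are the study conditions the package is exercised under:
#' three cohorts of 100 samples, 2000 genes in 200 equally sized modules,
#' cluster prevalences matching the pooled transcriptome collective
#' (30/24/46%), module archetype shifts of 2 log2 units on 30% of modules,
#' residual noise SD 1 log2 unit, additive cohort batch effects of SD 0.5,
#' and cluster hazard ratios (1.8, 1.5, 1) relative to cluster 3.
#'
#' @param n_cohorts,samples_per_cohort,n_genes,n_modules sizes.
#' @param cluster_props length-3 vector of cluster probabilities (sums to 1).
#' @param archetypes 3 x n_modules matrix of module mean shifts (log2 units).
#' @param batch_sd SD of the additive per-(cohort, gene) offset.
#' @param noise_sd SD of the residual log2 noise (> 0).
#' @param hazard_ratios length-3 vector of cluster hazards relative to
#'   cluster 3 (all > 0).
#' @param mut_genes named list: gene -> length-3 vector of per-cluster
#'   mutation probabilities.
#' @param proteome_fraction fraction of genes quantified in the emulated
#'   proteome, in (0, 1].
#' @param seed integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cohorts = 3, samples_per_cohort = 100,
                       n_genes = 2000, n_modules = 200,
                       cluster_props = c(0.30, 0.24, 0.46),
                       archetypes = default_archetypes(n_modules),
                       batch_sd = 0.5, noise_sd = 1,
                       hazard_ratios = c(1.8, 1.5, 1),
                       mut_genes = list(TP53 = c(0.25, 0.60, 0.15),
                                        FGFR3 = c(0.10, 0.05, 0.45),
                                        RB1   = c(0.10, 0.30, 0.05)),
                       proteome_fraction = 0.3, seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              samples_per_cohort = as.integer(samples_per_cohort),
              n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              cluster_props = cluster_props, archetypes = archetypes,
              batch_sd = batch_sd, noise_sd = noise_sd,
              hazard_ratios = hazard_ratios, mut_genes = mut_genes,
              proteome_fraction = proteome_fraction, seed = as.integer(seed))
  if (cfg$n_cohorts < 1 || cfg$samples_per_cohort < 1 || cfg$n_genes < 1 ||
      cfg$n_modules < 0)
    stop("sizes must be positive")
  if (length(cfg$cluster_props) != 3 || any(cfg$cluster_props < 0) ||
      abs(sum(cfg$cluster_props) - 1) > 1e-8)
    stop("cluster_props must be 3 nonnegative values summing to 1")
  if (!is.matrix(cfg$archetypes) || nrow(cfg$archetypes) != 3 ||
      ncol(cfg$archetypes) != cfg$n_modules)
    stop("archetypes must be a 3 x n_modules matrix")
  if (cfg$batch_sd < 0 || cfg$noise_sd < 0)
    stop("batch_sd and noise_sd must be >= 0")
  if (length(cfg$hazard_ratios) != 3 || any(cfg$hazard_ratios <= 0))
    stop("hazard_ratios must be 3 positive values")
  if (cfg$proteome_fraction <= 0 || cfg$proteome_fraction > 1)
    stop("proteome_fraction must be in (0, 1]")
  if (anyDuplicated(names(cfg$mut_genes))) stop("duplicate mutation gene names")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-cohort expression study with known cluster structure
#'
#' Each gene belongs to at most one module; its expression is
#' `baseline + archetype[cluster, module] + batch(cohort, gene) + noise`,
#' with gene baselines drawn once from Normal(8, 2) log2 units, additive
#' Normal(0, batch_sd) cohort offsets per gene, and Normal(0, noise_sd)
#' residual noise. Latent cluster labels are i.i.d. from `cluster_props`.
#' A proteome companion of the last cohort is generated by subsampling
#' `proteome_fraction` of the genes and adding Normal(0, 1.5 * noise_sd)
#' extra noise. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_study`: `cohorts` (list of
#'   [expression_matrix()]), `proteome` (expression_matrix), and `truth`
#'   (per-sample labels, per-gene module map, archetypes, config).
#' @export
simulate_multicohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "multicohort"))
  genes <- sprintf("gene_%04d", seq_len(config$n_genes))
  module_size <- if (config$n_modules > 0) config$n_genes %/% config$n_modules else 0
  module_of <- rep(NA_integer_, config$n_genes)
  if (module_size > 0)
    module_of[seq_len(module_size * config$n_modules)] <-
      rep(seq_len(config$n_modules), each = module_size)
  baseline <- stats::rnorm(config$n_genes, 8, 2)

  cohorts <- vector("list", config$n_cohorts)
  labels <- character(0)
  for (ci in seq_len(config$n_cohorts)) {
    cid <- sprintf("cohort_%02d", ci)
    sids <- sprintf("%s_s%03d", cid, seq_len(config$samples_per_cohort))
    cl <- sample.int(3, config$samples_per_cohort, replace = TRUE,
                     prob = config$cluster_props)
    batch <- if (config$batch_sd > 0)
      stats::rnorm(config$n_genes, 0, config$batch_sd) else numeric(config$n_genes)
    shift <- matrix(0, config$n_genes, config$samples_per_cohort)
    in_mod <- !is.na(module_of)
    if (any(in_mod))
      shift[in_mod, ] <- config$archetypes[cbind(
        rep(cl, each = sum(in_mod)),
        rep(module_of[in_mod], times = length(cl)))]
    eps <- matrix(stats::rnorm(config$n_genes * config$samples_per_cohort,
                               0, config$noise_sd),
                  config$n_genes, config$samples_per_cohort)
    values <- baseline + shift + batch + eps
    dimnames(values) <- list(genes, sids)
    cohorts[[ci]] <- expression_matrix(values, cohort_id = cid)
    labels <- c(labels, stats::setNames(cl, sids))
  }
  names(cohorts) <- vapply(cohorts, `[[`, character(1), "cohort_id")

  prot_src <- cohorts[[config$n_cohorts]]
  n_prot <- max(1L, round(config$proteome_fraction * config$n_genes))
  prot_genes <- sort(sample.int(config$n_genes, n_prot))
  prot_values <- prot_src$values[prot_genes, , drop = FALSE] +
    matrix(stats::rnorm(n_prot * ncol(prot_src$values), 0, 1.5 * config$noise_sd),
           n_prot, ncol(prot_src$values))
  colnames(prot_values) <- paste0("prot_", colnames(prot_values))
  proteome <- expression_matrix(prot_values,
                                cohort_id = paste0(prot_src$cohort_id, "_proteome"),
                                modality = "proteome")

  labels <- stats::setNames(as.integer(labels), names(labels))
  structure(list(cohorts = cohorts, proteome = proteome,
                 truth = list(labels = labels, module_of =
                                stats::setNames(module_of, genes),
                              archetypes = config$archetypes, config = config)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d cohorts x %d samples, %d genes, proteome of %d features\n",
              length(x$cohorts), ncol(x$cohorts[[1]]$values),
              nrow(x$cohorts[[1]]$values), nrow(x$proteome$values)))
  invisible(x)
}

#' Simulate survival times with cluster-proportional hazards
#'
#' Exponential event times whose hazard scales with the cluster's hazard
#' ratio relative to cluster 3, plus independent uniform censoring.
#'
#' @param labels integer cluster labels in 1..3.
#' @param hazard_ratios length-3 hazards relative to cluster 3.
#' @param baseline_median median survival (days) of cluster 3.
#' @param censor_rate expected fraction censored, in [0, 1).
#' @param seed integer seed.
#' @return `data.frame` with `sample`, `time` (days), `event` (0/1), `cluster`.
#' @export
simulate_survival <- function(labels, hazard_ratios = c(1.8, 1.5, 1),
                              baseline_median = 1200, censor_rate = 0.3,
                              seed = 1L) {
  if (!length(labels)) stop("empty label vector")
  stopifnot(length(hazard_ratios) == 3, all(hazard_ratios > 0),
            censor_rate >= 0, censor_rate < 1)
  set.seed(stage_seed(seed, "survival"))
  n <- length(labels)
  base_rate <- log(2) / baseline_median
  rate <- base_rate * hazard_ratios[labels]
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    # uniform censoring window calibrated to yield roughly censor_rate censoring
    cmax <- stats::quantile(t_event, probs = min(1, 2 * (1 - censor_rate)))
    t_cens <- stats::runif(n, 0, max(cmax, .Machine$double.eps))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  data.frame(sample = if (!is.null(names(labels))) names(labels) else
               sprintf("s%04d", seq_len(n)),
             time = time, event = event, cluster = as.integer(labels),
             stringsAsFactors = FALSE)
}

#' Simulate a binary somatic-mutation matrix with planted cluster enrichment
#'
#' Planted genes are Bernoulli with cluster-specific rates; background genes
#' mutate independently of the clusters at `background_rate`.
#'
#' @param labels integer cluster labels in 1..3 (named by sample).
#' @param mut_genes named list: gene -> length-3 per-cluster probabilities.
#' @param n_background_genes number of cluster-independent genes.
#' @param background_rate mutation probability of background genes.
#' @param seed integer seed.
#' @return Binary gene x sample matrix.
#' @export
simulate_mutations <- function(labels, mut_genes = list(TP53 = c(0.25, 0.6, 0.15)),
                               n_background_genes = 50, background_rate = 0.1,
                               seed = 1L) {
  stopifnot(length(labels) >= 1)
  probs <- unlist(mut_genes)
  if (any(probs < 0 | probs > 1)) stop("mutation probabilities must be in [0, 1]")
  if (anyDuplicated(names(mut_genes))) stop("duplicate gene names")
  set.seed(stage_seed(seed, "mutations"))
  n <- length(labels)
  planted <- t(vapply(mut_genes, function(p)
    stats::rbinom(n, 1, p[labels]), integer(n)))
  bg <- matrix(stats::rbinom(n_background_genes * n, 1, background_rate),
               nrow = n_background_genes)
  out <- rbind(planted, bg)
  rownames(out) <- c(names(mut_genes),
                     sprintf("bg_gene_%03d", seq_len(n_background_genes)))
  colnames(out) <- if (!is.null(names(labels))) names(labels) else
    sprintf("s%04d", seq_len(n))
  out
}

#' Simulate CRISPR knockout scores and a drug screen for labelled cell lines
#'
#' Chronos-style scores are sign-flipped so positive means growth inhibition:
#' background genes are Normal(0, score_sd); each planted essential gene has
#' mean `essential_effect` in its target cluster only. The drug response is a
#' sparse linear function of the expression matrix plus Normal noise.
#'
#' @param labels_celllines integer cluster labels of the cell lines (named).
#' @param expr optional cell-line expression matrix (genes x lines) used to
#'   generate drug responses; simulated Normal(8, 2) baseline expression with
#'   unit noise when absent.
#' @param essential_genes named list: gene -> target cluster (1..3).
#' @param essential_effect planted mean score in the target cluster.
#' @param score_sd residual score SD.
#' @param n_background_genes count of non-essential genes.
#' @param n_drugs number of simulated drugs.
#' @param n_causal_genes genes with nonzero response coefficients per drug.
#' @param response_noise_sd drug-response noise SD.
#' @param seed integer seed.
#' @return List with `chronos` (line x gene matrix), `labels`, `drug_response`
#'   (line x drug matrix), `drug_truth` (coefficients per drug), `expr`.
#' @export
simulate_screens <- function(labels_celllines,
                             expr = NULL,
                             essential_genes = list(ess_c1 = 1, ess_c2 = 2, ess_c3 = 3),
                             essential_effect = 1.0, score_sd = 0.15,
                             n_background_genes = 50,
                             n_drugs = 3, n_causal_genes = 5,
                             response_noise_sd = 0.3, seed = 1L) {
  n <- length(labels_celllines)
  if (n < 2) stop("need at least 2 cell lines")
  if (min(table(factor(labels_celllines, levels = 1:3))) < 2)
    warning("fewer than 2 cell lines in some cluster; bootstrap stages will drop it")
  set.seed(stage_seed(seed, "screens"))
  lines <- if (!is.null(names(labels_celllines))) names(labels_celllines) else
    sprintf("line_%03d", seq_len(n))
  genes <- c(names(essential_genes),
             sprintf("bgko_%03d", seq_len(n_background_genes)))
  chronos <- matrix(stats::rnorm(n * length(genes), 0, score_sd), nrow = n,
                    dimnames = list(lines, genes))
  for (g in names(essential_genes)) {
    tgt <- labels_celllines == essential_genes[[g]]
    chronos[tgt, g] <- chronos[tgt, g] + essential_effect
  }
  if (is.null(expr)) {
    ng <- 100L
    expr <- matrix(stats::rnorm(ng * n, 8, 2), nrow = ng,
                   dimnames = list(sprintf("gene_%04d", seq_len(ng)), lines))
  }
  expr <- as_values(expr)
  drug_truth <- vector("list", n_drugs)
  resp <- matrix(0, n, n_drugs,
                 dimnames = list(lines, sprintf("drug_%02d", seq_len(n_drugs))))
  for (d in seq_len(n_drugs)) {
    causal <- sample.int(nrow(expr), min(n_causal_genes, nrow(expr)))
    beta <- stats::setNames(stats::rnorm(length(causal), 0, 1),
                            rownames(expr)[causal])
    resp[, d] <- drop(crossprod(expr[causal, , drop = FALSE], beta)) +
      stats::rnorm(n, 0, response_noise_sd)
    drug_truth[[d]] <- beta
  }
  names(drug_truth) <- colnames(resp)
  list(chronos = chronos, labels = labels_celllines, drug_response = resp,
       drug_truth = drug_truth, expr = expr)
}

#' Write a synthetic study to disk
#'
#' One expression TSV per cohort plus a truth JSON; round-trips through
#' [read_expression()].
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (co in study$cohorts)
    write_expression(co, file.path(dir, paste0(co$cohort_id, ".tsv")))
  write_expression(study$proteome, file.path(dir, "proteome.tsv"))
  jsonlite::write_json(
    list(labels = as.list(study$truth$labels),
         module_of = as.list(study$truth$module_of)),
    file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
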