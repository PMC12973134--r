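#' End-to-end synthetic-study pipeline
#'
#' Runs the full discovery-and-transfer flow on simulated data: generate the
#' multi-cohort study, pool with batch adjustment, train the SOM metagenes on
#' the training cohort, score all cohorts by ssGSEA, cluster the training
#' cohort with hard-threshold regularised k-means, transfer the labels to the
#' held-out cohorts with the inverse distance-weighted k-NN classifier and to
#' the synthetic proteome with a multinomial elastic net, and score recovery
#' of the simulated truth.
#'
#' @param config a [sim_config()]; its seed drives every stage through
#'   [stage_seed()].
#' @param grid SOM grid.
#' @param som_epochs SOM training epochs.
#' @param k,lambda HTK cluster count and shrinkage.
#' @param n_init HTK restarts.
#' @param knn_k neighbour count for transfer.
#' @param stages character subset of
#'   `c("simulate","metagenes","score","cluster","transfer","proteome")`;
#'   later stages require earlier ones.
#' @return List of class `pipeline_run` with per-stage outputs, recovery
#'   `metrics` (`ari`, `knn_accuracy`, `enet_accuracy`) and a `manifest`
#'   (parameters, stage hashes, timings).
#' @export
run_pipeline <- function(config = sim_config(),
                         grid = som_grid(16, 16, "toroidal"),
                         som_epochs = 40, k = 3, lambda = 0.1,
                         n_init = 20, knn_k = 7,
                         stages = c("simulate", "metagenes", "score",
                                    "cluster", "transfer", "proteome")) {
  stages <- match.arg(stages, several.ok = TRUE)
  t0 <- Sys.time()
  out <- list()
  manifest <- list(parameters = list(seed = config$seed, som_epochs = som_epochs,
                                     k = k, lambda = lambda, n_init = n_init,
                                     knn_k = knn_k,
                                     grid = paste0(grid$rows, "x", grid$cols)),
                   stages = list())
  mark <- function(name, obj) {
    manifest$stages[[name]] <<- list(
      hash = object_hash(obj),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  study <- simulate_multicohort(config)
  out$study <- study
  mark("simulate", study$truth$labels)
  if (!any(c("metagenes", "score", "cluster", "transfer", "proteome") %in% stages)) {
    out$manifest <- manifest
    class(out) <- "pipeline_run"
    return(out)
  }

  train <- study$cohorts[[1]]
  if ("metagenes" %in% stages) {
    Xs <- standardise_rows(train$values)
    som <- train_som(Xs, grid, epochs = som_epochs,
                     seed = stage_seed(config$seed, "pipeline_som"))
    metagenes <- extract_metagenes(som, Xs)
    out$som <- som
    out$metagenes <- metagenes
    mark("metagenes", metagenes$assignment)
  }
  if ("score" %in% stages) {
    pooled <- batch_adjust(study$cohorts)
    cohort_of <- attr(pooled, "sample_cohort")
    scores <- lapply(names(study$cohorts), function(cid) {
      sub <- pooled$values[, cohort_of == cid, drop = FALSE]
      ssgsea_scores(sub, out$metagenes$sets)
    })
    names(scores) <- names(study$cohorts)
    out$scores <- scores
    mark("score", lapply(scores, dim))
  }
  if ("cluster" %in% stages) {
    htk <- fit_htkmeans(out$scores[[1]], k = k, lambda = lambda,
                        n_init = n_init,
                        seed = stage_seed(config$seed, "pipeline_htk"))
    out$htk <- htk
    truth_tr <- study$truth$labels[names(htk$assignments)]
    out$metrics$ari <- adjusted_rand(htk$assignments, truth_tr)
    # majority-vote map from HTK labels to latent truth labels, so transfer
    # accuracies are computable despite arbitrary cluster numbering
    out$label_map <- vapply(seq_len(k), function(c) {
      tt <- truth_tr[htk$assignments == c]
      if (!length(tt)) return(NA_integer_)
      as.integer(names(sort(table(tt), decreasing = TRUE))[1])
    }, integer(1))
    mark("cluster", htk$assignments)
  }
  if ("transfer" %in% stages) {
    # transfer happens in the discriminative metagene space the regularised
    # clustering selected; inactive metagenes carry no cluster signal
    act <- names(which(out$htk$active_features))
    clf <- knn_classifier(out$scores[[1]][, act, drop = FALSE],
                          out$htk$assignments, k = knn_k)
    held <- names(study$cohorts)[-1]
    acc <- vapply(held, function(cid) {
      asg <- knn_assign(clf, out$scores[[cid]][, act, drop = FALSE])
      mean(out$label_map[asg$labels] ==
             study$truth$labels[names(asg$labels)])
    }, numeric(1))
    out$knn_accuracy_by_cohort <- acc
    out$metrics$knn_accuracy <- mean(acc)
    mark("transfer", acc)
  }
  if ("proteome" %in% stages) {
    prot <- study$proteome
    shared <- intersect(rownames(train$values), rownames(prot$values))
    Xtr <- t(train$values[shared, , drop = FALSE])
    enet <- fit_enet(Xtr, out$htk$assignments[rownames(Xtr)],
                     seed = stage_seed(config$seed, "pipeline_enet"))
    prot_labels_truth <- study$truth$labels[
      sub("^prot_", "", colnames(prot$values))]
    asg <- enet_assign(enet, t(prot$values[shared, , drop = FALSE]))
    out$enet <- enet
    out$proteome_assignment <- asg
    out$metrics$enet_accuracy <-
      mean(out$label_map[asg$labels] == prot_labels_truth)
    mark("proteome", asg$labels)
  }
  manifest$total_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out$manifest <- manifest
  class(out) <- "pipeline_run"
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  if (!is.null(x$metrics))
    for (m in names(x$metrics))
      cat(sprintf("  %s: %.3f\n", m, x$metrics[[m]]))
  cat(sprintf("  stages: %s\n", paste(names(x$manifest$stages), collapse = ", ")))
  invisible(x)
}
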