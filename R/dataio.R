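#' Log2 expression matrix with cohort metadata
#'
#' The universal carrier for transcriptome, proteome and cell-line data:
#' a feature x sample matrix of log2-scale values plus a cohort identifier
#' and a modality tag.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   row and column names.
#' @param cohort_id single string identifying the cohort.
#' @param modality one of `"transcriptome"`, `"proteome"`, `"cellline"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, cohort_id,
                              modality = c("transcriptome", "proteome", "cellline")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs feature and sample names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  structure(list(values = values, cohort_id = as.character(cohort_id),
                 modality = modality),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> cohort '%s' (%s): %d features x %d samples\n",
              x$cohort_id, x$modality, nrow(x$values), ncol(x$values)))
  invisible(x)
}

## Accept either an expression_matrix or a bare named matrix.
as_values <- function(X) {
  if (inherits(X, "expression_matrix")) X$values else as.matrix(X)
}

#' Read an expression matrix from TSV or GCT
#'
#' The TSV dialect is features x samples with a header row of sample ids; the
#' GCT dialect additionally carries a two-line preamble (`#1.2`, dimensions)
#' and a `Description` column, both of which are skipped.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @param cohort_id,modality passed to [expression_matrix()]; `cohort_id`
#'   defaults to the file name.
#' @param na_tokens strings parsed as missing values.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "gct"),
                            cohort_id = sub("\\.[^.]+$", "", basename(path)),
                            modality = "transcriptome",
                            na_tokens = c("", "NA", "NaN")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  skip <- if (format == "gct") 2L else 0L
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          na.strings = na_tokens, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (format == "gct" && tolower(names(df)[1]) == "description")
    df <- df[, -1, drop = FALSE]
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric expression columns: ", paste(names(df)[bad], collapse = ", "))
  values <- as.matrix(df)
  rownames(values) <- ids
  expression_matrix(values, cohort_id = cohort_id, modality = modality)
}

#' Write an expression matrix as TSV
#'
#' Round-trips with [read_expression()] value-identically.
#'
#' @param X an [expression_matrix()] or named matrix.
#' @param path output path.
#' @param feature_col name of the leading feature-id column.
#' @export
write_expression <- function(X, path, feature_col = "feature") {
  values <- as_values(X)
  df <- data.frame(feature = rownames(values), values, check.names = FALSE)
  names(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' One set per line: name, description (tolerated when absent), then member
#' ids. Empty sets and duplicate set names are rejected.
#'
#' @param path file path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in ", path)
  sets <- lapply(parts, function(p) {
    genes <- p[-1]
    # second column is an optional free-text description
    if (length(genes) >= 1) genes <- genes[-1]
    genes[nzchar(genes)]
  })
  names(sets) <- nm
  if (any(lengths(sets) == 0)) stop("empty gene set(s) in ", path)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' Features missing in more than `max_missing_fraction` of samples are
#' dropped; every remaining missing cell is replaced by the mean of the `k`
#' nearest features (Euclidean distance over the samples observed in both
#' features) that are observed in that sample.
#'
#' @param X [expression_matrix()] or matrix, features x samples.
#' @param max_missing_fraction drop threshold for feature missingness.
#' @param k number of neighbour features averaged per imputation.
#' @return Object of the same type with no missing values.
#' @export
knn_impute <- function(X, max_missing_fraction = 0.5, k = 10) {
  em <- inherits(X, "expression_matrix")
  values <- as_values(X)
  if (any(colSums(!is.na(values)) == 0)) stop("all-missing sample(s) present")
  frac <- rowMeans(is.na(values))
  values <- values[frac <= max_missing_fraction, , drop = FALSE]
  miss_rows <- which(rowSums(is.na(values)) > 0)
  for (i in miss_rows) {
    xi <- values[i, ]
    obs_i <- !is.na(xi)
    # mean squared difference over shared observed samples, per candidate
    d2 <- rep(NA_real_, nrow(values))
    for (j in seq_len(nrow(values))) {
      if (j == i) next
      shared <- obs_i & !is.na(values[j, ])
      if (!any(shared)) next
      d2[j] <- mean((xi[shared] - values[j, shared])^2)
    }
    for (s in which(is.na(xi))) {
      cand <- which(!is.na(values[, s]) & !is.na(d2))
      if (!length(cand)) stop("cannot impute sample ", colnames(values)[s])
      nb <- cand[order(d2[cand], cand)][seq_len(min(k, length(cand)))]
      values[i, s] <- mean(values[nb, s])
    }
  }
  if (em) expression_matrix(values, X$cohort_id, X$modality) else values
}

#' Pool cohorts with cross-cohort batch adjustment
#'
#' Restricts to the features shared by all cohorts, then removes additive and
#' multiplicative cohort effects. The default `center_scale` method z-scores
#' each feature within each cohort (population variance, so the adjustment is
#' exactly idempotent) and restores the pooled per-feature mean and SD;
#' `combat` delegates to `sva::ComBat` when that package is installed.
#'
#' @param cohorts list of [expression_matrix()] objects (>= 2).
#' @param method `"center_scale"` or `"combat"`.
#' @return An [expression_matrix()] over pooled samples, with a
#'   `sample_cohort` attribute mapping samples to their source cohort.
#' @export
batch_adjust <- function(cohorts, method = c("center_scale", "combat")) {
  method <- match.arg(method)
  if (length(cohorts) < 2) stop("batch adjustment needs >= 2 cohorts")
  mats <- lapply(cohorts, as_values)
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (!length(shared)) stop("cohorts share no features")
  mats <- lapply(mats, function(m) m[shared, , drop = FALSE])
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  # drop features with zero variance inside any cohort (cannot be scaled there)
  zv <- Reduce(`|`, lapply(mats, function(m) apply(m, 1, pop_sd) == 0))
  if (any(zv)) {
    warning(sum(zv), " zero-variance feature(s) within a cohort dropped")
    mats <- lapply(mats, function(m) m[!zv, , drop = FALSE])
    shared <- shared[!zv]
  }
  pooled_raw <- do.call(cbind, mats)
  cohort_of <- rep(vapply(cohorts, function(x)
    if (inherits(x, "expression_matrix")) x$cohort_id else "cohort",
    character(1)), vapply(mats, ncol, integer(1)))
  if (method == "combat") {
    if (!requireNamespace("sva", quietly = TRUE))
      stop("method 'combat' needs the sva package")
    adj <- sva::ComBat(pooled_raw, batch = cohort_of)
  } else {
    gm <- rowMeans(pooled_raw)
    gs <- apply(pooled_raw, 1, pop_sd)
    gs[gs == 0] <- 1
    adj <- do.call(cbind, lapply(mats, function(m) {
      cm <- rowMeans(m)
      cs <- apply(m, 1, pop_sd)
      cs[cs == 0] <- 1
      (m - cm) / cs * gs + gm
    }))
  }
  out <- expression_matrix(adj, cohort_id = "pooled",
                           modality = if (inherits(cohorts[[1]], "expression_matrix"))
                             cohorts[[1]]$modality else "transcriptome")
  attr(out, "sample_cohort") <- stats::setNames(cohort_of, colnames(adj))
  out
}

#' Harmonise muscle invasiveness from pathological stage
#'
#' Ta, T1, Tis and CIS tumours are non-muscle-invasive (NMIBC), T2-T4
#' specimens muscle-invasive (MIBC); an explicit invasiveness field, when
#' present, takes precedence over the stage-derived label.
#'
#' @param stage character vector of pathological T-stage tokens.
#' @param invasiveness optional explicit labels (`"NMIBC"`/`"MIBC"`), `NA`
#'   where unavailable.
#' @return Character vector with levels `NMIBC`, `MIBC`, `unknown`.
#' @export
harmonise_invasiveness <- function(stage, invasiveness = NULL) {
  tok <- toupper(trimws(as.character(stage)))
  nmibc <- c("TA", "T1", "TIS", "CIS")
  mibc <- c("T2", "T3", "T4", "T2-4", "T3-4", "T2A", "T2B", "T3A", "T3B", "T4A", "T4B")
  out <- ifelse(tok %in% nmibc, "NMIBC", ifelse(tok %in% mibc, "MIBC", "unknown"))
  unknown_tok <- !is.na(tok) & !(tok %in% c(nmibc, mibc))
  if (any(unknown_tok))
    warning("unrecognised stage token(s): ",
            paste(unique(tok[unknown_tok]), collapse = ", "))
  out[is.na(tok)] <- "unknown"
  if (!is.null(invasiveness)) {
    inv <- toupper(as.character(invasiveness))
    keep <- !is.na(inv) & inv %in% c("NMIBC", "MIBC")
    out[keep] <- inv[keep]
  }
  out
}
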