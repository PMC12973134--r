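# Shared fixtures, built in code.

# Small feature x sample matrix with named dims.
toy_matrix <- function(n_feat = 5, n_samp = 4, seed = 1, mean = 8, sd = 2) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * n_samp, mean, sd), n_feat, n_samp,
              dimnames = list(sprintf("g%02d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  m
}

# Two well-separated gene blocks for SOM block-recovery checks.
block_gene_matrix <- function(block_size = 30, n_samp = 20, sep = 4, seed = 3) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(block_size * n_samp, sep / 2), block_size),
             matrix(rnorm(block_size * n_samp, -sep / 2), block_size))
  dimnames(X) <- list(sprintf("g%03d", seq_len(2 * block_size)),
                      sprintf("s%02d", seq_len(n_samp)))
  X
}

# Independent brute-force ssGSEA oracle: literal walk down the ranked list.
ssgsea_brute <- function(x, set, alpha = 0.25) {
  n <- length(x)
  r <- rank(-x, ties.method = "average")        # 1 = highest expression
  ord <- order(r, seq_len(n))
  in_set <- names(x) %in% set
  w <- (n - r + 1)^alpha
  num <- 0; den_in <- sum(w[in_set]); cum_in <- 0; cum_out <- 0
  es <- 0
  for (i in ord) {
    if (in_set[i]) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1
    es <- es + cum_in / den_in - cum_out / (n - sum(in_set))
  }
  unname(es)
}

# Random GPR rule AST generator for property tests.
random_gpr <- function(genes, depth = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  build <- function(d) {
    if (d == 0 || runif(1) < 0.35)
      return(sample(genes, 1))
    op <- sample(c("and", "or"), 1)
    k <- sample(2:3, 1)
    parts <- vapply(seq_len(k), function(i) {
      s <- build(d - 1)
      if (grepl(" ", s)) paste0("(", s, ")") else s
    }, character(1))
    paste(parts, collapse = paste0(" ", op, " "))
  }
  build(depth)
}

# Tiny in-memory GPR model from rule strings.
gpr_model_from_rules <- function(rules, subsystems = NULL) {
  if (is.null(subsystems)) subsystems <- rep("unassigned", length(rules))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(reactions = lapply(seq_along(rules), function(i)
      list(id = sprintf("R%03d", i), rule = rules[[i]],
           subsystem = subsystems[[i]]))),
    path, auto_unbox = TRUE)
  read_gpr_model(path)
}
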