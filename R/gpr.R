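#' Parse a gene-protein-reaction (GPR) boolean rule
#'
#' Grammar: gene identifiers combined with `and` / `or` (case-insensitive)
#' and parentheses; `and` binds tighter than `or`. AND nodes model enzyme
#' complexes (all members required), OR nodes isozymes (any member
#' suffices). The AST round-trips to a canonical string via
#' [deparse_gpr()].
#'
#' @param rule_string the rule, e.g. `"g1 and (g2 or g3)"`.
#' @return A nested list AST: `list(op = "gene", gene = id)` leaves and
#'   `list(op = "and"/"or", args = list(...))` nodes.
#' @export
parse_gpr <- function(rule_string) {
  if (!is.character(rule_string) || length(rule_string) != 1 ||
      !nzchar(trimws(rule_string)))
    stop("empty rule")
  tokens <- gpr_tokens(rule_string)
  state <- new.env(parent = emptyenv())
  state$tokens <- tokens
  state$pos <- 1L
  ast <- gpr_expr(state)
  if (state$pos <= length(state$tokens))
    stop("unexpected token '", state$tokens[state$pos], "' in rule: ", rule_string)
  ast
}

gpr_tokens <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  tok <- strsplit(trimws(s), "\\s+")[[1]]
  tok[nzchar(tok)]
}

gpr_peek <- function(st) if (st$pos <= length(st$tokens)) st$tokens[st$pos] else NA_character_

gpr_take <- function(st) {
  t <- gpr_peek(st)
  st$pos <- st$pos + 1L
  t
}

## Same-operator children are spliced in (AND/OR are associative), so the
## AST is canonical and deparse/parse round-trips exactly.
gpr_node <- function(op, args) {
  flat <- list()
  for (a in args) {
    if (!identical(a$op, "gene") && identical(a$op, op))
      flat <- c(flat, a$args)
    else flat <- c(flat, list(a))
  }
  if (length(flat) == 1) flat[[1]] else list(op = op, args = flat)
}

## expr := term (OR term)*
gpr_expr <- function(st) {
  args <- list(gpr_term(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    gpr_take(st)
    args <- c(args, list(gpr_term(st)))
  }
  gpr_node("or", args)
}

## term := factor (AND factor)*
gpr_term <- function(st) {
  args <- list(gpr_factor(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    gpr_take(st)
    args <- c(args, list(gpr_factor(st)))
  }
  gpr_node("and", args)
}

## factor := GENE | ( expr )
gpr_factor <- function(st) {
  t <- gpr_take(st)
  if (is.na(t)) stop("unexpected end of rule")
  if (t == "(") {
    inner <- gpr_expr(st)
    close <- gpr_take(st)
    if (is.na(close) || close != ")") stop("unbalanced parentheses")
    return(inner)
  }
  if (t == ")" || tolower(t) %in% c("and", "or"))
    stop("unexpected token '", t, "'")
  list(op = "gene", gene = t)
}

#' @rdname parse_gpr
#' @param ast a parsed rule.
#' @return `deparse_gpr()`: the canonical string form.
#' @export
deparse_gpr <- function(ast) {
  if (ast$op == "gene") return(ast$gene)
  parts <- vapply(ast$args, function(a) {
    s <- deparse_gpr(a)
    # parenthesise OR under AND to preserve precedence
    if (ast$op == "and" && a$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", ast$op, " "))
}

gpr_genes <- function(ast) {
  if (ast$op == "gene") return(ast$gene)
  unique(unlist(lapply(ast$args, gpr_genes)))
}

## Evaluate an AST on a gene x draw matrix of linear fold-changes.
## AND = minimum of operands (scarcest complex member), OR = sum (isozymes).
gpr_eval <- function(ast, fc) {
  if (ast$op == "gene") {
    if (ast$gene %in% rownames(fc)) return(fc[ast$gene, ])
    return(rep(1, ncol(fc)))  # missing genes are neutral
  }
  vals <- lapply(ast$args, gpr_eval, fc = fc)
  if (ast$op == "and") do.call(pmin, vals) else Reduce(`+`, vals)
}

#' Load a metabolic model from JSON
#'
#' Schema: `reactions` = array of `{id, rule, subsystem}`. Rules are parsed
#' with [parse_gpr()]; reactions without a subsystem go to `"unassigned"`.
#'
#' @param path JSON file path.
#' @return Object of class `gpr_model`: `reactions` (id -> list(rule AST,
#'   subsystem)), `subsystems` (name -> reaction ids).
#' @export
read_gpr_model <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(js$reactions)) stop("model JSON lacks a 'reactions' array")
  reactions <- lapply(js$reactions, function(r) {
    list(id = r$id, rule = parse_gpr(r$rule),
         subsystem = if (is.null(r$subsystem)) "unassigned" else r$subsystem)
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(names(reactions))) stop("duplicate reaction ids")
  subsystems <- split(names(reactions),
                      vapply(reactions, `[[`, character(1), "subsystem"))
  structure(list(reactions = reactions, subsystems = subsystems),
            class = "gpr_model")
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf("<gpr_model> %d reactions in %d subsystems\n",
              length(x$reactions), length(x$subsystems)))
  invisible(x)
}

#' Monte-Carlo metabolic reaction activity from differential expression
#'
#' Per draw, each gene's log2 fold change is sampled from
#' Normal(estimate, SE) and converted to a linear fold change `2^x`; each
#' reaction's rule is evaluated with AND = minimum and OR = sum of operand
#' values and normalised by the same rule evaluated at the all-ones baseline,
#' so every well-formed rule has fold change exactly 1 under zero
#' differential expression. Draws are summarised as the median, the central
#' 95% interval, and an add-one-corrected two-sided Monte-Carlo p-value
#' (doubled tail fraction of draws on the opposite side of 1, capped at 1).
#' A reaction is `activated` when the interval lies above 1, `inhibited`
#' below 1, otherwise `unchanged`.
#'
#' @param model a [read_gpr_model()] model.
#' @param log2fc named per-gene log2 fold-change estimates.
#' @param se named per-gene standard errors (>= 0, same names as `log2fc`).
#' @param n_draws Monte-Carlo draws (>= 100).
#' @param seed integer seed.
#' @return `data.frame` per reaction: `fold_change` (median), `lower`,
#'   `upper`, `p`, `status`, plus `n_draws`/`seed` attributes.
#' @export
reaction_activity <- function(model, log2fc, se, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(model, "gpr_model"))
  if (n_draws < 100) stop("n_draws must be >= 100")
  se <- se[names(log2fc)]
  if (anyNA(se) || any(se < 0)) stop("negative or missing SE")
  need <- unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$rule))))
  have <- intersect(need, names(log2fc))
  if (length(have) < length(need))
    message(length(need) - length(have),
            " rule gene(s) absent from estimates; treated as fold-change 1")
  set.seed(stage_seed(seed, "gpr_mc"))
  draws <- matrix(stats::rnorm(length(have) * n_draws, log2fc[have], se[have]),
                  nrow = length(have), dimnames = list(have, NULL))
  fc <- 2^draws
  ones <- matrix(1, length(have), 1, dimnames = list(have, NULL))
  rows <- lapply(model$reactions, function(r) {
    base <- gpr_eval(r$rule, ones)
    vals <- gpr_eval(r$rule, fc) / base
    med <- stats::median(vals)
    ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
    lower_tail <- sum(vals < 1)
    upper_tail <- sum(vals > 1)
    opp <- if (med >= 1) lower_tail else upper_tail
    p <- min(1, 2 * (1 + opp) / (n_draws + 1))
    status <- if (ci[1] > 1) "activated" else if (ci[2] < 1) "inhibited" else "unchanged"
    data.frame(reaction = r$id, subsystem = r$subsystem, fold_change = med,
               lower = ci[1], upper = ci[2], p = p, status = status,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, "BH")
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  out
}

#' Subsystem enrichment of activated or inhibited reactions
#'
#' Compares each subsystem's count of significant reactions with `n_draws`
#' uniform draws (without replacement) of the same number of reactions from
#' the whole reaction pool. OR is the observed count over the null mean;
#' significance requires FDR q < 0.05 and OR >= 1.44 (closed bound).
#'
#' @param activity a [reaction_activity()] table.
#' @param model the matching [read_gpr_model()] model.
#' @param direction `"activated"` or `"inhibited"`.
#' @param n_draws random draws for the null.
#' @param seed integer seed.
#' @param q_max,or_min significance thresholds.
#' @return `data.frame` per subsystem: observed, expected, `or`, `p`, `q`,
#'   `significant`.
#' @export
subsystem_enrichment <- function(activity, model, direction = c("activated", "inhibited"),
                                 n_draws = 10000, seed = 1L,
                                 q_max = 0.05, or_min = 1.44) {
  direction <- match.arg(direction)
  sig <- activity$reaction[activity$status == direction]
  if (!length(sig)) stop("no significant reactions in direction ", direction)
  pool <- names(model$reactions)
  subs <- names(model$subsystems)
  sub_of <- vapply(model$reactions, `[[`, character(1), "subsystem")
  obs <- table(factor(sub_of[sig], levels = subs))
  set.seed(stage_seed(seed, "subsystem_enrichment"))
  m <- length(sig)
  counts <- matrix(0L, n_draws, length(subs), dimnames = list(NULL, subs))
  for (b in seq_len(n_draws)) {
    draw <- sample(pool, m)
    counts[b, ] <- table(factor(sub_of[draw], levels = subs))
  }
  expected <- colMeans(counts)
  p <- (1 + colSums(counts >= rep(obs, each = n_draws))) / (n_draws + 1)
  or <- ifelse(expected > 0, as.numeric(obs) / expected, NA)
  out <- data.frame(subsystem = subs, direction = direction,
                    observed = as.integer(obs), expected = expected,
                    or = or, p = as.numeric(p), row.names = NULL)
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- !is.na(out$or) & out$q < q_max & out$or >= or_min
  out
}
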