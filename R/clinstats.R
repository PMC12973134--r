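#' Chi-square test with Cramer's V effect size
#'
#' Pearson chi-square without continuity correction (printed effect sizes in
#' clinical contingency tables only reproduce without the correction), with
#' `V = sqrt(chi2 / (N * min(r - 1, c - 1)))`. Empty rows and columns are
#' dropped first; an `unknown` category, when present among the labels, is
#' excluded before testing.
#'
#' @param table r x c matrix of nonnegative counts.
#' @param drop_unknown exclude rows/columns labelled `"unknown"`.
#' @return List: `chi2`, `df`, `p`, `V`.
#' @export
cramers_v <- function(table, drop_unknown = TRUE) {
  m <- as.matrix(table)
  if (drop_unknown) {
    if (!is.null(rownames(m))) m <- m[tolower(rownames(m)) != "unknown", , drop = FALSE]
    if (!is.null(colnames(m))) m <- m[, tolower(colnames(m)) != "unknown", drop = FALSE]
  }
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("contingency table must be at least 2x2 after filtering")
  ch <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  V <- sqrt(unname(ch$statistic) / (sum(m) * min(nrow(m) - 1, ncol(m) - 1)))
  list(chi2 = unname(ch$statistic), df = unname(ch$parameter),
       p = unname(ch$p.value), V = V)
}

#' Mann-Whitney test with the rank-biserial r effect size
#'
#' Two-sided normal-approximation Mann-Whitney U with tie correction;
#' `r = |Z| / sqrt(n_A + n_B)`. Fully tied data return Z = 0, r = 0.
#'
#' @param x_a,x_b numeric samples.
#' @return List: `U`, `Z`, `p`, `r`.
#' @export
mw_effect <- function(x_a, x_b) {
  if (!length(x_a) || !length(x_b)) stop("both groups must be non-empty")
  n1 <- length(x_a); n2 <- length(x_b); n <- n1 + n2
  r <- rank(c(x_a, x_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1, r = 0))
  Z <- (U - mu) / sqrt(sigma2)
  list(U = U, Z = Z, p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE),
       r = abs(Z) / sqrt(n))
}

#' Weighted log-rank test with Peto-Peto weights
#'
#' k-group weighted log-rank chi-square. The Peto-Peto weight at each event
#' time is the left-continuous pooled survival estimate, so early deaths
#' carry more weight than under the plain log-rank test; `weights = "unit"`
#' recovers the standard log-rank statistic exactly.
#'
#' @param time,event survival times (days) and 0/1 event flags.
#' @param group group labels (>= 2 groups with >= 1 event overall).
#' @param weights `"peto"` or `"unit"`.
#' @return List: `statistic`, `df`, `p`.
#' @export
peto_peto <- function(time, event, group, weights = c("peto", "unit")) {
  weights <- match.arg(weights)
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(time >= 0), all(event %in% 0:1))
  g <- factor(group)
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 groups")
  if (sum(event) == 0) stop("no events")
  times <- sort(unique(time[event == 1]))
  # left-continuous pooled survival estimate for the Peto-Peto weight
  n_at <- function(t) sum(time >= t)
  surv_left <- local({
    s <- 1
    out <- numeric(length(times))
    for (i in seq_along(times)) {
      out[i] <- s
      ni <- n_at(times[i])
      di <- sum(time == times[i] & event == 1)
      s <- s * (1 - di / ni)
    }
    out
  })
  U <- numeric(k - 1)
  V <- matrix(0, k - 1, k - 1)
  for (i in seq_along(times)) {
    t <- times[i]
    ni <- n_at(t)
    di <- sum(time == t & event == 1)
    w <- if (weights == "peto") surv_left[i] else 1
    ng <- vapply(levels(g), function(l) sum(time >= t & g == l), numeric(1))
    dg <- vapply(levels(g), function(l)
      sum(time == t & event == 1 & g == l), numeric(1))
    e <- di * ng / ni
    U <- U + w * (dg[-k] - e[-k])
    if (ni > 1) {
      mult <- di * (ni - di) / (ni - 1)
      for (a in seq_len(k - 1)) for (b in seq_len(k - 1)) {
        V[a, b] <- V[a, b] + w^2 * mult *
          (ng[a] / ni) * ((a == b) - ng[b] / ni)
      }
    }
  }
  stat <- drop(t(U) %*% solve(V, U))
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Kaplan-Meier survival-time quantiles with 95% confidence intervals
#'
#' Product-limit estimates per group; the q-survival quantile is the first
#' time the survival curve falls to or below q (so the 25% quantile is the
#' time by which 75% of the group has died). Quantiles the curve never
#' reaches are `NA` (not reached). CIs are the log-transformed Greenwood
#' intervals of `survival::survfit`.
#'
#' @param time,event,group as in [peto_peto()].
#' @param probs survival levels.
#' @return `data.frame`: group, survival quantile, time, lower, upper.
#' @export
km_quantiles <- function(time, event, group, probs = c(0.25, 0.5, 0.75)) {
  g <- factor(group)
  first_crossing <- function(tt, ss, q) {
    hit <- which(!is.na(ss) & ss <= q)
    if (!length(hit)) NA_real_ else tt[min(hit)]
  }
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    sel <- g == lv
    fit <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1,
                             conf.type = "log")
    rows <- lapply(probs, function(q) {
      data.frame(group = lv, survival_quantile = q,
                 time = first_crossing(fit$time, fit$surv, q),
                 # CI for the quantile time: the same crossing rule applied
                 # to the Greenwood bands (the lower survival band crosses
                 # earlier, bounding the quantile time from below)
                 lower = first_crossing(fit$time, fit$lower, q),
                 upper = first_crossing(fit$time, fit$upper, q),
                 row.names = NULL)
    })
    do.call(rbind, rows)
  }))
  out
}

#' Univariable Cox proportional-hazards model per group
#'
#' Delegates the partial-likelihood fit to `survival::coxph`; hazard ratios
#' are reported against the reference level with Wald 95% CIs. Groups
#' without events are flagged unstable.
#'
#' @param time,event,group as in [peto_peto()].
#' @param reference reference group level.
#' @return `data.frame`: group, HR, lower, upper, p, unstable flag.
#' @export
cox_univariable <- function(time, event, group, reference = NULL) {
  g <- factor(group)
  if (!is.null(reference)) {
    if (!reference %in% levels(g)) stop("reference level absent")
    g <- stats::relevel(g, ref = as.character(reference))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ g)
  s <- summary(fit)
  hr <- s$conf.int[, "exp(coef)"]
  lo <- s$conf.int[, "lower .95"]; up <- s$conf.int[, "upper .95"]
  p <- s$coefficients[, "Pr(>|z|)"]
  lev <- sub("^g", "", rownames(s$conf.int))
  ev <- tapply(event, g, sum)
  data.frame(group = lev, reference = levels(g)[1],
             HR = as.numeric(hr), lower = as.numeric(lo),
             upper = as.numeric(up), p = as.numeric(p),
             unstable = ev[lev] == 0, row.names = NULL)
}
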