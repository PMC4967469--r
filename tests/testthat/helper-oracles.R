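# independent reference implementations used as test oracles

# literal step-up BH reference
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# slow per-sample formula evaluator (independent of evaluate_formula)
slow_eval <- function(formula, row) {
  if (length(formula$clauses) == 0) return(formula$form == "CNF")
  vals <- vapply(formula$clauses, function(cl) {
    lit <- vapply(cl, function(l) {
      neg <- substr(l, 1, 1) == "!"
      f <- if (neg) substring(l, 2) else l
      v <- row[[f]]
      if (neg) v == 0 else v == 1
    }, logical(1))
    if (formula$form == "DNF") all(lit) else any(lit)
  }, logical(1))
  if (formula$form == "DNF") any(vals) else all(vals)
}

# exhaustive brute-force optimum of the weighted logic objective for one
# complexity (k clauses of up to m distinct-feature literals, DNF, "up to"
# semantics) subject to the training specificity constraint; truth-value
# semantics, independent of the package's prediction-matrix library
oracle_logic_optimum <- function(X, labels, weights, k, m,
                                 min_specificity = 0.8) {
  nf <- ncol(X)
  feats <- colnames(X)
  Lb <- cbind(X == 1, X == 0)
  colnames(Lb) <- c(feats, paste0("!", feats))
  # every AND-clause of 1..m literals over distinct features
  clause_lits <- list()
  for (s in seq_len(min(m, nf))) {
    pols <- as.matrix(expand.grid(rep(list(c(0L, 1L)), s)))
    for (fs in asplit(combn(nf, s), 2)) {
      for (g in seq_len(nrow(pols)))
        clause_lits[[length(clause_lits) + 1L]] <- fs + nf * pols[g, ]
    }
  }
  clause_pred <- vapply(clause_lits, function(cl)
    rowSums(!Lb[, cl, drop = FALSE]) == 0, logical(nrow(X)))
  n0 <- sum(!labels)
  best <- Inf; feasible <- FALSE
  consider <- function(pred) {
    spec <- if (n0 > 0) sum(!pred & !labels) / n0 else 1
    if (spec < min_specificity - 1e-9) return(invisible(NULL))
    feasible <<- TRUE
    err <- sum(weights[pred != labels])
    if (err < best) best <<- err
    invisible(NULL)
  }
  if (k > 1 && m == 1) {
    # pure OR family: subsets of 1..k literals (both polarities allowed)
    for (s in seq_len(min(k, 2 * nf)))
      for (i in asplit(combn(2 * nf, s), 2))
        consider(rowSums(Lb[, i, drop = FALSE]) > 0)
  } else if (k == 1) {
    for (j in seq_along(clause_lits)) consider(clause_pred[, j])
  } else {
    stopifnot(k == 2, m == 2)
    nc <- length(clause_lits)
    for (j in seq_len(nc)) consider(clause_pred[, j])
    for (pair in asplit(combn(nc, 2), 2))
      consider(clause_pred[, pair[1]] | clause_pred[, pair[2]])
  }
  list(best = best, feasible = feasible)
}

# one-sided (greater) Fisher exact p via the hypergeometric sum
fisher_greater_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  sum(dhyper(seq(a, min(m, k)), m, n, k))
}

# equal-posterior crossing of a two-component Gaussian mixture by grid search
grid_posterior_crossing <- function(mu, sig, w, lo, hi) {
  g <- seq(lo, hi, length.out = 20001)
  d <- log(w[1]) + dnorm(g, mu[1], sig[1], log = TRUE) -
    log(w[2]) - dnorm(g, mu[2], sig[2], log = TRUE)
  g[which.min(abs(d))]
}
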