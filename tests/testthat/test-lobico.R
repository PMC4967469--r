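test_that("binarize_and_weight conserves half the mass per class", {
  set.seed(1)
  for (i in 1:20) {
    ic <- rnorm(sample(10:60, 1), 2, 1.5)
    theta <- runif(1, 0, 4)
    if (all(ic <= theta) || all(ic > theta)) next
    bw <- binarize_and_weight(ic, theta)
    expect_equal(sum(bw$weights[bw$labels]), 0.5, tolerance = 1e-12)
    expect_equal(sum(bw$weights[!bw$labels]), 0.5, tolerance = 1e-12)
  }
  # a sample exactly at theta carries zero weight
  bw <- binarize_and_weight(c(0, 1, 2, 3), theta = 1)
  expect_equal(unname(bw$weights[2]), 0)
  expect_true(bw$labels[2])
  expect_error(binarize_and_weight(c(1, 2), theta = 0), "non-empty")
})

test_that("evaluate_formula matches truth-table semantics", {
  X <- matrix(c(1, 0), 1, 2, dimnames = list("s1", c("A", "B")))
  expect_true(evaluate_formula(logic_formula(list("A", "B")), X)[["s1"]])
  f_id <- logic_formula(list("A"))
  Xr <- matrix(c(1, 0, 1), 3, 1, dimnames = list(paste0("s", 1:3), "A"))
  expect_equal(unname(evaluate_formula(f_id, Xr)), c(TRUE, FALSE, TRUE))

  # all 16 rows over 4 features vs the independent slow evaluator
  rows <- as.matrix(expand.grid(rep(list(0:1), 4)))
  colnames(rows) <- LETTERS[1:4]
  rownames(rows) <- sprintf("r%02d", 1:16)
  set.seed(2)
  for (i in 1:25) {
    form <- sample(c("DNF", "CNF"), 1)
    n_cl <- sample(1:3, 1)
    clauses <- lapply(seq_len(n_cl), function(j) {
      fs <- sample(LETTERS[1:4], sample(1:3, 1))
      ifelse(runif(length(fs)) < 0.5, paste0("!", fs), fs)
    })
    f <- logic_formula(clauses, form = form)
    fast <- evaluate_formula(f, rows)
    slow <- vapply(seq_len(16), function(r) slow_eval(f, as.list(rows[r, ])),
                   logical(1))
    expect_equal(unname(fast), slow)
  }

  # missing feature values propagate as NA
  Xna <- matrix(c(1, NA), 2, 1, dimnames = list(c("s1", "s2"), "A"))
  out <- evaluate_formula(logic_formula(list("A")), Xna)
  expect_true(is.na(out[["s2"]]))
  expect_error(evaluate_formula(logic_formula(list("Z")), Xna), "absent")
})

test_that("a perfect single-feature signal is fit with zero error", {
  set.seed(3)
  X <- matrix(rbinom(200, 1, 0.3), 40, 5,
              dimnames = list(sprintf("s%02d", 1:40), paste0("f", 1:5)))
  labels <- X[, "f3"] == 1
  if (sum(labels) < 2) labels[1:2] <- TRUE
  w <- rep(1 / 40, 40)
  fit <- fit_logic_model(X, labels, w, complexity = c(1, 1))
  expect_equal(format(fit$formula), "f3")
  expect_equal(fit$train_error, 0)
  expect_true(fit$feasible)
})

test_that("fit_logic_model attains the exhaustive-oracle optimum", {
  set.seed(4)
  comps <- lobico_complexities()
  for (i in 1:8) {
    n <- sample(15:30, 1); p <- sample(4:6, 1)
    X <- matrix(rbinom(n * p, 1, 0.4), n, p,
                dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:p)))
    ic <- rnorm(n)
    theta <- quantile(ic, 0.4)
    bw <- binarize_and_weight(ic, theta)
    cp <- comps[[sample(8, 1)]]
    fit <- fit_logic_model(X, bw$labels, bw$weights,
                           complexity = cp, min_specificity = 0.8)
    oracle <- oracle_logic_optimum(X, bw$labels, bw$weights, cp$k, cp$m, 0.8)
    if (!oracle$feasible) {
      expect_false(fit$feasible)
    } else {
      expect_equal(fit$train_error, oracle$best, tolerance = 1e-9)
    }
  }
})

test_that("the optimal objective is non-increasing with nested complexity", {
  set.seed(5)
  X <- matrix(rbinom(25 * 6, 1, 0.4), 25, 6,
              dimnames = list(sprintf("s%02d", 1:25), paste0("f", 1:6)))
  ic <- rnorm(25)
  bw <- binarize_and_weight(ic, median(ic))
  err_of <- function(k, m) fit_logic_model(X, bw$labels, bw$weights,
                                           complexity = c(k, m),
                                           min_specificity = 0)$train_error
  base <- err_of(1, 1)
  for (cp in list(c(1, 2), c(2, 1), c(1, 4), c(4, 1), c(2, 2)))
    expect_lte(err_of(cp[1], cp[2]), base + 1e-12)
})

test_that("every returned non-null model satisfies the specificity floor", {
  set.seed(6)
  for (i in 1:10) {
    n <- 40
    X <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
                dimnames = list(sprintf("s%02d", 1:n), paste0("f", 1:6)))
    ic <- rnorm(n)
    bw <- binarize_and_weight(ic, quantile(ic, 0.3))
    fit <- fit_logic_model(X, bw$labels, bw$weights, complexity = c(2, 2),
                           min_specificity = 0.8)
    if (fit$feasible) expect_gte(fit$specificity, 0.8 - 1e-9)
  }
})

test_that("cross-validation selects the simplest complexity for clean signals", {
  set.seed(7)
  X <- matrix(rbinom(300 * 6, 1, 0.25), 300, 6,
              dimnames = list(sprintf("s%03d", 1:300), paste0("f", 1:6)))
  ic <- ifelse(X[, "f2"] == 1, 1, 4) + rnorm(300, sd = 1e-3)
  names(ic) <- rownames(X)
  res <- lobico_cv(X, ic, theta = 2.5, seed = 1)
  expect_equal(res$selected, "single")
  expect_lt(res$cv_error[["single"]], 0.01)
  expect_equal(format(res$model$formula), "f2")

  res2 <- lobico_cv(X, ic, theta = 2.5, seed = 1)
  expect_identical(res2$cv_error, res$cv_error)
  expect_identical(format(res2$model$formula), format(res$model$formula))
})

test_that("drugs with too few sensitive lines are skipped", {
  set.seed(8)
  X <- matrix(rbinom(100, 1, 0.3), 20, 5,
              dimnames = list(sprintf("s%02d", 1:20), paste0("f", 1:5)))
  ic <- c(rep(0, 3), rep(4, 17))
  names(ic) <- rownames(X)
  expect_error(lobico_cv(X, ic, theta = 1), "skipped")
})

test_that("permutation p-values respect their bounds", {
  set.seed(9)
  X <- matrix(rbinom(60 * 4, 1, 0.4), 60, 4,
              dimnames = list(sprintf("s%02d", 1:60), paste0("f", 1:4)))
  ic <- setNames(rnorm(60, 2), rownames(X))
  res <- lobico_cv(X, ic, theta = 2, seed = 2)
  p <- permutation_significance(res, X, ic, n_perm = 19, seed = 3)
  expect_gte(as.numeric(p), 1 / 20)
  expect_lte(as.numeric(p), 1)
  expect_error(permutation_significance(res, X, ic, n_perm = 5), "19")
})

test_that("model metrics reproduce the worked recall percentages", {
  # 22 sensitive lines; the OR model captures 10 (plus 3 false positives),
  # the single-predictor model captures 7
  n <- 60
  labels <- c(rep(TRUE, 22), rep(FALSE, 38))
  X <- cbind(or_marker = c(rep(1, 10), rep(0, 12), rep(1, 3), rep(0, 35)),
             single_marker = c(rep(1, 7), rep(0, 15), rep(1, 2), rep(0, 36)))
  rownames(X) <- sprintf("s%02d", 1:n)
  m_or <- model_metrics(logic_formula(list("or_marker")), X, labels)
  m_single <- model_metrics(logic_formula(list("single_marker")), X, labels)
  expect_equal(round(100 * m_or$recall), 45)
  expect_equal(round(100 * m_single$recall), 32)

  perfect <- model_metrics(logic_formula(list("or_marker")), X,
                           X[, "or_marker"] == 1)
  expect_equal(unlist(perfect[1:3]),
               c(precision = 1, recall = 1, specificity = 1))

  null_m <- model_metrics(logic_formula(list()), X, labels)
  expect_equal(null_m$recall, 0)
  expect_equal(null_m$specificity, 1)
  expect_true(is.na(null_m$precision))
})

test_that("feature importance concentrates, conserves and zeroes correctly", {
  set.seed(10)
  X <- matrix(rbinom(300 * 5, 1, 0.3), 300, 5,
              dimnames = list(sprintf("s%03d", 1:300), paste0("f", 1:5)))
  ic <- setNames(ifelse(X[, "f1"] == 1, 0.5, 4) + rnorm(300, sd = 0.2),
                 rownames(X))
  res <- lobico_cv(X, ic, theta = 2, seed = 4)
  fi <- feature_importance(list(d1 = res),
                           classes = setNames(rep("CG", 5), paste0("f", 1:5)))
  expect_equal(sum(fi$feature), 1)
  expect_equal(unname(fi$feature["f1"]), 1)
  expect_false("f5" %in% names(fi$feature))
  expect_equal(sum(fi$category), sum(fi$feature))
})
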