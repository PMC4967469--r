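test_that("effect sizes match hand arithmetic and behave under transformation", {
  es <- effect_sizes(c(1, 2, 3), c(3, 4, 5))
  expect_equal(es$cohens_d, -2)
  expect_equal(es$glass_pos, 2)
  expect_equal(es$glass_neg, 2)

  same <- effect_sizes(c(2, 2, 2), c(2, 2, 2))
  expect_equal(unlist(same), c(cohens_d = 0, glass_pos = 0, glass_neg = 0))

  # shift invariance and common scaling
  set.seed(1)
  pos <- rnorm(10); neg <- rnorm(12, 1)
  base <- effect_sizes(pos, neg)
  shifted <- effect_sizes(pos + 7, neg + 7)
  expect_equal(unlist(shifted), unlist(base))
  scaled <- effect_sizes(3 * pos, 3 * neg)
  expect_equal(unlist(scaled), unlist(base))

  # zero-variance group yields NA for its Glass delta
  zv <- effect_sizes(c(1, 1, 1), c(2, 3, 4))
  expect_true(is.na(zv$glass_pos))
  expect_false(is.na(zv$glass_neg))
})

test_that("the covariate-free association F-test equals the pooled t-test", {
  set.seed(2)
  for (i in 1:10) {
    x <- rbinom(40, 1, 0.4)
    if (sum(x) < 3 || sum(1 - x) < 3) next
    y <- rnorm(40) + 0.5 * x
    p_f <- fit_association(y, x)$p_value
    p_t <- t.test(y[x == 1], y[x == 0], var.equal = TRUE)$p.value
    expect_equal(p_f, p_t, tolerance = 1e-12)
  }
})

test_that("association p-values are uniform under the null", {
  set.seed(3)
  ps <- vapply(1:1000, function(i) {
    y <- rnorm(200)
    x <- rbinom(200, 1, 0.3)
    tissue <- sample(c("A", "B", "C"), 200, replace = TRUE)
    fit_association(y, x, data.frame(cancer_type = tissue))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a CFE confounded with its covariate is dropped, not tested", {
  y <- rnorm(40)
  tissue <- rep(c("A", "B"), each = 20)
  x <- as.integer(tissue == "A")
  res <- fit_association(y, x, data.frame(cancer_type = tissue))
  expect_true(is.na(res$p_value))
  expect_equal(res$reason, "confounded")
})

test_that("small groups are skipped with a recorded reason", {
  res <- fit_association(rnorm(20), c(1, 1, rep(0, 18)))
  expect_true(is.na(res$p_value))
  expect_equal(res$reason, "group_size")
  expect_equal(res$n_pos, 2)
})

test_that("bh_fdr reproduces the step-up reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_reference(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("run_scan flags planted effects and is order-invariant", {
  sc <- planted_screen(seed = 6)
  scan <- run_scan(sc$responses, sc$cohort$cell_lines, mode = "pan_cancer")
  hit <- scan[scan$cfe_id == "f001", ]
  expect_true(hit$significant)
  expect_true(hit$large_effect)
  expect_equal(hit$direction, "sensitizing")
  expect_equal(hit$n_pos + hit$n_neg, 300)

  # permuting input rows and columns leaves the result identical
  perm_rows <- sample(rownames(sc$responses$ic50))
  perm_cols <- sample(colnames(sc$cohort$cell_lines$values))
  resp2 <- drug_response(sc$responses$ic50[perm_rows, , drop = FALSE],
                         sc$responses$max_conc)
  alt2 <- alteration_matrix(
    sc$cohort$cell_lines$values[perm_rows, perm_cols],
    sc$cohort$cell_lines$annotations)
  scan2 <- run_scan(resp2, alt2, mode = "pan_cancer")
  expect_equal(scan2, scan, ignore_attr = TRUE)
})

test_that("a single-test scan has fdr equal to its p-value", {
  sc <- planted_screen(n_lines = 60, n_carriers = 12, n_cfes = 1, seed = 7)
  scan <- run_scan(sc$responses, sc$cohort$cell_lines, mode = "pan_cancer")
  expect_equal(nrow(scan), 1L)
  expect_equal(scan$fdr, scan$p_value)
})

test_that("null scans produce p < 1e-3 hits at the binomial rate and BH limits FWER", {
  n_hits <- integer(10); any_rej <- logical(10)
  for (i in 1:10) {
    ns <- null_screen(n_lines = 160, n_cfes = 20, n_drugs = 10,
                      seed = 500 + i)
    scan <- run_scan(ns$responses, ns$cohort$cell_lines, mode = "pan_cancer")
    n_hits[i] <- sum(scan$p_value < 1e-3)
    any_rej[i] <- any(scan$significant)
  }
  # ~200 tests/scan: expected 0.2 raw p<1e-3 hits per scan
  expect_lt(mean(n_hits), 1.5)
  # BH at 25% makes any-rejection events no more frequent than 25% + noise
  expect_lt(mean(any_rej), 0.5)
})

test_that("cancer-specific scans restrict samples and enforce the size gate", {
  cfg <- default_sim_config(seed = 9)
  co <- simulate_cohort(cfg)
  dr <- simulate_drug_response(co$cell_lines, cfg)
  scan <- run_scan(dr$responses, co$cell_lines, mode = "cancer_specific",
                   cancer_type = "BRCA")
  expect_true(all(scan$n_pos + scan$n_neg <= 50))
  expect_match(scan$analysis[1], "cancer_specific:BRCA")
  expect_error(run_scan(dr$responses, co$cell_lines, mode = "cancer_specific",
                        cancer_type = "missing_type"),
               "more than 15")
})

test_that("downsampling retains everything at full size and is seed-stable", {
  sc <- planted_screen(n_lines = 120, n_carriers = 25, n_cfes = 8, seed = 10)
  ds <- downsample_experiment(sc$responses, sc$cohort$cell_lines,
                              sizes = c(120, 60), reps = 2, seed = 3,
                              mode = "pan_cancer")
  expect_true(all(ds$retention_sig[ds$size == 120] == 1))
  ds2 <- downsample_experiment(sc$responses, sc$cohort$cell_lines,
                               sizes = c(120, 60), reps = 2, seed = 3,
                               mode = "pan_cancer")
  expect_identical(ds, ds2)
  expect_error(downsample_experiment(sc$responses, sc$cohort$cell_lines,
                                     sizes = 500, reps = 1, seed = 1,
                                     mode = "pan_cancer"),
               "cohort size")
})

test_that("downsampling retention decreases with subset size on average", {
  sc <- planted_screen(n_lines = 150, n_carriers = 20, n_cfes = 10, seed = 11)
  # several moderate effects so retention is graded, not saturated
  cfg <- sc$config
  cfg$additive_effects <- data.frame(
    drug_id = "d001", cfe_id = sprintf("f%03d", 1:4),
    beta = c(-1, -0.8, -0.6, -0.5))
  co <- simulate_cohort(cfg)
  dr <- simulate_drug_response(co$cell_lines, cfg)
  ds <- downsample_experiment(dr$responses, co$cell_lines,
                              sizes = c(120, 50), reps = 20, seed = 4,
                              mode = "pan_cancer")
  m <- tapply(ds$retention_sig, ds$size, mean)
  expect_gte(m[["120"]], m[["50"]])
})

test_that("cross-study validation: self-agreement, sign flips, permuted nulls", {
  sc <- planted_screen(n_lines = 200, n_carriers = 40, n_cfes = 12, seed = 12)
  cfg <- sc$config
  cfg$additive_effects <- data.frame(
    drug_id = "d001", cfe_id = sprintf("f%03d", 1:3), beta = c(-1.5, -1, 1))
  co <- simulate_cohort(cfg)
  dr <- simulate_drug_response(co$cell_lines, cfg)
  a <- run_scan(dr$responses, co$cell_lines, mode = "pan_cancer")

  self <- cross_study_validate(a, a)
  expect_equal(self$pearson_signed_logp, 1)
  expect_equal(self$validation_rate_sensitizing, 1)
  expect_equal(self$validation_rate_resistance, 1)

  flipped <- a
  flipped$delta_mean <- -flipped$delta_mean
  expect_lt(cross_study_validate(a, flipped)$pearson_signed_logp, 0)

  ns <- null_screen(n_lines = 200, n_cfes = 12, n_drugs = 1, seed = 13)
  resp_b <- drug_response(ns$responses$ic50, ns$responses$max_conc)
  colnames(resp_b$ic50) <- "d001"
  names(resp_b$max_conc) <- "d001"
  b <- run_scan(resp_b, co$cell_lines, mode = "pan_cancer")
  perm <- cross_study_validate(a, b)
  rates <- c(perm$validation_rate_sensitizing, perm$validation_rate_resistance)
  expect_true(all(rates[!is.na(rates)] <= 0.25))

  expect_error(cross_study_validate(a[1:4, ], a[1:4, ]), "at least 10")
})
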