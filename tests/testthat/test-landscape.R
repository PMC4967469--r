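paired_cohort <- function(seed = 1) {
  co <- simulate_cohort(concordance_sim_config(seed = seed))
  list(co = co,
       cm = profile_matrix(frequency_profiles(co$cell_lines)),
       tm = profile_matrix(frequency_profiles(co$tumors)))
}

test_that("frequency profiles are per-type column means over observed entries", {
  v <- matrix(c(1, 1, 1, 1, 1,
                0, 1, NA, 1, 0), ncol = 2,
              dimnames = list(sprintf("s%d", 1:5), c("f1", "f2")))
  am <- alteration_matrix(v, data.frame(
    sample_id = sprintf("s%d", 1:5), cohort = "tumor",
    cancer_type = c("A", "A", "A", "B", "B"), msi = "MSS"))
  fp <- frequency_profiles(am)
  get <- function(ct, f) fp$frequency[fp$cancer_type == ct & fp$cfe_id == f]
  expect_equal(get("A", "f1"), 1)            # saturated column
  expect_equal(get("A", "f2"), 0.5)          # NA excluded from denominator
  expect_equal(get("B", "f2"), 0.5)
  expect_equal(unique(fp$n_samples[fp$cancer_type == "A"]), 3)
})

test_that("profile correlations: identity, symmetry, orthogonal toys", {
  m <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 2, 3,
              dimnames = list(c("A", "B"), c("f1", "f2", "f3")))
  cc <- profile_correlation(m, m)
  expect_equal(diag(cc), c(A = 1, B = 1))
  expect_equal(cc, t(cc))
  expect_lt(cc["A", "B"], 0)  # near-orthogonal indicator profiles
})

test_that("nearest-neighbor matching is exact for identical cohorts and monotone in k", {
  pc <- paired_cohort(seed = 3)
  self <- nn_tissue_match(pc$tm, pc$tm, k = 1)
  expect_equal(self$accuracy, 1)

  acc_k <- vapply(1:3, function(k) nn_tissue_match(pc$cm, pc$tm, k)$accuracy,
                  numeric(1))
  expect_true(all(diff(acc_k) >= 0))
})

test_that("pathway frequency concordance matches hand computation", {
  # 3 types x 2 pathways, tumors == cell lines except one type
  v_t <- matrix(c(1, 0, 0, 1, 0, 0,
                  0, 1, 0, 0, 1, 1), ncol = 2,
                dimnames = list(sprintf("t%d", 1:6), c("f1", "f2")))
  ann_t <- data.frame(sample_id = sprintf("t%d", 1:6), cohort = "tumor",
                      cancer_type = rep(c("A", "B", "C"), each = 2),
                      msi = "MSS")
  v_c <- v_t; rownames(v_c) <- sprintf("c%d", 1:6)
  ann_c <- transform(ann_t, sample_id = sprintf("c%d", 1:6),
                     cohort = "cell_line")
  tum <- alteration_matrix(v_t, ann_t)
  cl <- alteration_matrix(v_c, ann_c)
  pmap <- data.frame(pathway = c("p1", "p2"), cfe_id = c("f1", "f2"))
  res <- pathway_frequency_correlation(tum, cl, pmap)
  expect_equal(res$per_pathway$r, c(1, 1))
  expect_equal(res$median_r, 1)

  # hand check of the fractions behind the correlation, pathway p1 type A
  expect_equal(mean(rowSums(v_t[1:2, "f1", drop = FALSE]) > 0), 0.5)

  # union bound: pathway fraction >= max single-CFE frequency in it
  pc <- paired_cohort(seed = 4)
  pmap2 <- toy_pathway_map(pc$co$catalog, n_pathways = 5)
  fp <- frequency_profiles(pc$co$tumors)
  for (pw in unique(pmap2$pathway)[1:3]) {
    cfes <- pmap2$cfe_id[pmap2$pathway == pw]
    for (ct in rownames(pc$tm)) {
      rows <- pc$co$tumors$annotations$cancer_type == ct
      frac <- mean(rowSums(pc$co$tumors$values[rows, cfes, drop = FALSE]) > 0)
      expect_gte(frac + 1e-12, max(pc$tm[ct, cfes]))
    }
  }
})

test_that("global class assignment follows burden argmax with priority ties", {
  ids <- c("CG1", "CG2", "iCpG1", "RACS1_del", "RACS1_amp")
  classes <- c("CG", "CG", "iCpG", "RACS_del", "RACS_amp")
  catalog <- cfe_catalog(data.frame(cfe_id = ids, cfe_class = classes),
                         data.frame(cfe_id = ids, cancer_type = "A",
                                    frequency = 0.3),
                         mode = "pan_cancer")
  v <- rbind(s1 = c(1, 1, 0, 0, 0),   # pure CG burden -> M
             s2 = c(0, 0, 0, 0, 0),   # no events -> unclassified
             s3 = c(0, 0, 1, 0, 0),   # pure methylation -> H
             s4 = c(1, 0, 1, 0, 0))
  colnames(v) <- ids
  am <- alteration_matrix(v, data.frame(sample_id = rownames(v),
                                        cohort = "tumor", cancer_type = "A",
                                        msi = "MSS"))
  ga <- assign_global_class(am, catalog)
  expect_equal(ga$class[ga$sample_id == "s1"], "M")
  expect_true(is.na(ga$class[ga$sample_id == "s2"]))
  expect_equal(ga$class[ga$sample_id == "s3"], "H")
  # s4: CG count 1 / mean 0.75 = 1.33 < H 1 / 0.5 = 2 -> H
  expect_equal(ga$class[ga$sample_id == "s4"], "H")
  # every classified sample appears in exactly one class
  expect_equal(sum(!is.na(ga$class)), 3)
})

test_that("modal classes and concordance flags follow the priority rule", {
  t_assign <- data.frame(cancer_type = "A",
                         class = c("M", "M", "CD"))
  c_assign <- data.frame(cancer_type = "A",
                         class = c("M", "CD"))  # tie -> priority M
  cc <- class_concordance(t_assign, c_assign)
  expect_equal(cc$tumor_class, "M")
  expect_equal(cc$cell_class, "M")
  expect_true(cc$concordant)
})

test_that("matched synthetic cohorts recover tissue and class concordance", {
  pc <- paired_cohort(seed = 5)
  nn <- nn_tissue_match(pc$cm, pc$tm, k = 1)
  expect_gte(nn$accuracy, 0.9)
  cc <- class_concordance(
    assign_global_class(pc$co$tumors, pc$co$catalog),
    assign_global_class(pc$co$cell_lines, pc$co$catalog))
  expect_gte(attr(cc, "fraction_concordant"), 0.9)
})

test_that("stratification percentages count marker carriers correctly", {
  v <- rbind(t1 = c(1, 0, 0), t2 = c(1, 0, 0), t3 = c(0, 1, 0),
             t4 = c(0, 0, 0))
  colnames(v) <- c("A", "B", "C")
  am <- alteration_matrix(v, data.frame(sample_id = rownames(v),
                                        cohort = "tumor", cancer_type = "X",
                                        msi = "MSS"))
  empty <- stratification_landscape(am)
  expect_equal(nrow(empty), 0)

  sm <- data.frame(drug_id = "d1", cfe_id = "A")
  sl <- stratification_landscape(am, single_markers = sm)
  expect_equal(sl$percent[sl$drug_id == "d1"], 50)  # 2 of 4 tumors

  lm_a <- stratification_landscape(
    am, logic_markers = list(d1 = logic_formula(list("A"))))
  lm_ab <- stratification_landscape(
    am, logic_markers = list(d1 = logic_formula(list("A", "B"))))
  expect_gte(lm_ab$percent[lm_ab$drug_id == "d1"],
             lm_a$percent[lm_a$drug_id == "d1"])
  expect_equal(lm_ab$percent[lm_ab$drug_id == "d1"], 75)
  expect_true(all(sl$percent >= 0 & sl$percent <= 100))

  skipped <- stratification_landscape(
    am, single_markers = data.frame(drug_id = "d9", cfe_id = "ZZ"))
  expect_true("ZZ" %in% attr(skipped, "skipped_markers"))
})
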