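test_that("alteration matrix TSV round-trip preserves values and annotations", {
  v <- matrix(c(0L, 1L, 1L, 0L, 1L, 0L), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("f1", "f2")))
  am <- tiny_am(v)
  expect_equal(dim(am$values), c(3L, 2L))

  am2 <- random_am(n = 12, p = 7, seed = 3, na_frac = 0.1)
  mp <- tempfile(fileext = ".tsv"); ap <- tempfile(fileext = ".tsv")
  write_alteration_matrix(am2, mp, ap)
  back <- read_alteration_matrix(mp, ap)
  expect_identical(back$values, am2$values)
  expect_identical(back$annotations, am2$annotations)
})

test_that("malformed matrix entries are rejected naming the offending cell", {
  v <- matrix(c(0, 2, 1, 0), nrow = 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  expect_error(tiny_am(v), "s2.*f1")

  mp <- tempfile(fileext = ".tsv"); ap <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2", "s1\t0\t1", "s2\t2\t0"), mp)
  write.table(tiny_annotations(c("s1", "s2")), ap, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(read_alteration_matrix(mp, ap), "s2.*f1")
})

test_that("samples missing from the annotation table are rejected", {
  v <- matrix(0L, 2, 1, dimnames = list(c("s1", "s9"), "f1"))
  expect_error(alteration_matrix(v, tiny_annotations("s1")), "s9")
})

test_that("merge_catalogs unions ids, keeps frequencies, detects class conflicts", {
  a <- tiny_catalog(c("f01", "f02"), types = "LUAD")
  b <- tiny_catalog(c("f02", "f03"), types = "BRCA")
  m <- merge_catalogs(list(a, b))
  expect_equal(nrow(m$cfes), 3L)
  expect_equal(m$mode, "pan_cancer")
  expect_setequal(catalog_cancer_types(m)$f02, c("LUAD", "BRCA"))

  single <- merge_catalogs(list(a))
  expect_equal(single$cfes, a$cfes)
  expect_equal(single$frequency, a$frequency)

  conflict <- tiny_catalog("f01", classes = "RACS_amp", types = "BRCA")
  expect_error(merge_catalogs(list(a, conflict)), "conflicting")
})

test_that("merged catalog size equals the set union; merging is idempotent", {
  set.seed(11)
  cats <- lapply(1:10, function(i) {
    ids <- sprintf("f%02d", sample(30, sample(3:8, 1)))
    tiny_catalog(ids, types = LETTERS[i])
  })
  m <- merge_catalogs(cats)
  union_ids <- sort(unique(unlist(lapply(cats, function(c) c$cfes$cfe_id))))
  expect_identical(m$cfes$cfe_id, union_ids)

  again <- merge_catalogs(list(m, m))
  expect_identical(again$cfes, m$cfes)
  expect_identical(again$frequency, m$frequency)
})

test_that("filter_by_catalog subsets, zero-fills absent CFEs and reports coverage", {
  am <- random_am(n = 5, p = 5, seed = 2)
  cat3 <- tiny_catalog(c("f02", "f04", "f05"))
  out <- filter_by_catalog(am, cat3)
  expect_identical(colnames(out$values), c("f02", "f04", "f05"))
  expect_identical(out$values[, "f02"], am$values[, "f02"])

  cat_ab <- tiny_catalog(c("f01", "zzz"))
  out2 <- filter_by_catalog(am, cat_ab)
  expect_true(all(out2$values[, "zzz"] == 0))
  expect_identical(attr(out2, "coverage")$absent_cfes, "zzz")

  for (seed in 1:5) {
    set.seed(seed)
    am_r <- random_am(n = 4, p = 8, seed = seed)
    ids <- unique(c(sample(colnames(am_r$values), 4), "x1", "x2"))
    cv <- attr(filter_by_catalog(am_r, tiny_catalog(ids)), "coverage")
    expect_equal(cv$fraction,
                 length(intersect(ids, colnames(am_r$values))) / length(ids))
  }
  expect_warning(filter_by_catalog(am, tiny_catalog("nope")), "no catalog CFEs")
})

test_that("detect_informative_cpg rejects bad input and degenerate signals", {
  expect_error(detect_informative_cpg(c(0.5, 1.2, rep(0.3, 30))), "\\[0, 1\\]")
  expect_error(detect_informative_cpg(runif(10)), "30")
  expect_false(detect_informative_cpg(rep(0.5, 100))$informative)

  set.seed(4)
  uni <- pmin(pmax(rnorm(200, 0.1, 0.03), 0), 1)
  expect_false(detect_informative_cpg(uni)$informative)
})

test_that("bimodal methylation yields a threshold at the equal-posterior point", {
  set.seed(9)
  b <- pmin(pmax(c(rnorm(100, 0.1, 0.05), rnorm(100, 0.8, 0.05)), 0), 1)
  r <- detect_informative_cpg(b)
  expect_true(r$informative)
  expect_gt(r$threshold, 0.3)
  expect_lt(r$threshold, 0.6)
  # the returned threshold must sit where the fitted posteriors cross
  crossing <- grid_posterior_crossing(r$means, r$sds, r$weights,
                                      r$means[1], r$means[2])
  expect_equal(qlogis(r$threshold), crossing, tolerance = 1e-3)
})

test_that("unimodal islands are rarely flagged; planted thresholds recovered", {
  flags <- vapply(1:40, function(i) {
    set.seed(100 + i)
    detect_informative_cpg(pmin(pmax(rnorm(500, 0.2, 0.05), 0), 1))$informative
  }, logical(1))
  expect_lte(mean(flags), 0.05)

  # logit-normal two-component mixtures centered at beta 0.1 / 0.8 (the
  # generating model of the mixture fit); analytic crossing by grid oracle
  mu <- qlogis(c(0.1, 0.8)); sig <- c(0.56, 0.31); w <- c(0.5, 0.5)
  analytic <- plogis(grid_posterior_crossing(mu, sig, w, mu[1], mu[2]))
  errs <- vapply(1:40, function(i) {
    set.seed(200 + i)
    hi <- runif(500) < w[2]
    b <- plogis(rnorm(500, mean = ifelse(hi, mu[2], mu[1]),
                      sd = ifelse(hi, sig[2], sig[1])))
    r <- detect_informative_cpg(b)
    if (!r$informative) return(NA_real_)
    abs(r$threshold - analytic)
  }, numeric(1))
  expect_gte(mean(!is.na(errs) & errs <= 0.05), 0.95)
})

test_that("binarize_methylation uses a strict threshold and drops NA islands", {
  b <- matrix(c(0.9, 0.5, 0.2, 0.1, 0.7, 0.6), nrow = 3,
              dimnames = list(c("i1", "i2", "i3"), c("s1", "s2")))
  tab <- methylation_table(b, "LUAD")
  am <- binarize_methylation(tab, c(i1 = 0.5, i2 = 0.5, i3 = NA))
  expect_identical(colnames(am$values), c("i1", "i2"))
  expect_equal(am$values["s1", "i1"], 1L)   # 0.9 > 0.5
  expect_equal(am$values["s1", "i2"], 0L)   # 0.5 > 0.5 is FALSE (strict)

  set.seed(5)
  b2 <- matrix(runif(200), 10, 20,
               dimnames = list(sprintf("i%02d", 1:10), sprintf("s%02d", 1:20)))
  thr <- setNames(runif(10), rownames(b2))
  am2 <- binarize_methylation(methylation_table(b2, "OV"), thr)
  expect_equal(unname(colSums(am2$values)),
               unname(rowSums(b2 > thr)))
})

test_that("catalog TSV round-trip preserves classes, types and frequencies", {
  cat1 <- tiny_catalog(c("f01", "f02", "f03"),
                       classes = c("CG", "RACS_del", "iCpG"),
                       types = c("LUAD", "BRCA"), freqs = c(0.1, 0.2))
  path <- tempfile(fileext = ".tsv")
  write_cfe_catalog(cat1, path)
  back <- read_cfe_catalog(path)
  expect_equal(back$cfes, cat1$cfes)
  expect_equal(back$mode, cat1$mode)
  f1 <- cat1$frequency[order(cat1$frequency$cfe_id, cat1$frequency$cancer_type), ]
  f2 <- back$frequency[order(back$frequency$cfe_id, back$frequency$cancer_type), ]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f2, f1)
})
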