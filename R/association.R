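#' Effect sizes for a two-group drug response comparison
#'
#' Cohen's d is the mean difference over the pooled standard deviation
#' (`s_pooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, sample
#' standard deviations with `n - 1` denominators); the two Glass deltas are
#' the absolute mean difference over each group's own standard deviation.
#' Glass deltas are reported for both the altered and unaltered populations
#' because the large-effect gate requires both to exceed 1.
#'
#' @param pos ln IC50 values of carriers (altered samples), at least 2.
#' @param neg ln IC50 values of non-carriers, at least 2.
#' @return list with `cohens_d` (signed, negative = carriers more sensitive),
#'   `glass_pos` and `glass_neg` (non-negative). A zero-variance group yields
#'   `NA` for its Glass delta (and for Cohen's d when both variances vanish
#'   with unequal means); identical constant groups yield zeros.
#' @examples
#' effect_sizes(c(1, 2, 3), c(3, 4, 5))  # cohens_d = -2, both deltas = 2
#' @export
effect_sizes <- function(pos, neg) {
  stopifnot(length(pos) >= 2, length(neg) >= 2)
  md <- mean(pos) - mean(neg)
  s1 <- sd(pos); s2 <- sd(neg)
  sp <- sqrt(((length(pos) - 1) * s1^2 + (length(neg) - 1) * s2^2) /
               (length(pos) + length(neg) - 2))
  ratio <- function(num, den) {
    if (den > 0) num / den else if (num == 0) 0 else NA_real_
  }
  list(cohens_d = ratio(md, sp),
       glass_pos = ratio(abs(md), s1),
       glass_neg = ratio(abs(md), s2))
}

# drop covariate columns with a single observed level
usable_covariates <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0) return(NULL)
  keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1,
                 logical(1))
  if (!any(keep)) return(NULL)
  covariates[, keep, drop = FALSE]
}

# F-test of a binary term added last to an OLS fit (rank-deficiency aware)
anova_term_p <- function(y, x, Z, fit0 = NULL) {
  if (is.null(fit0)) fit0 <- lm.fit(Z, y)
  fit1 <- lm.fit(cbind(Z, cfe = x), y)
  if (fit1$rank <= fit0$rank)
    return(list(p_value = NA_real_, reason = "confounded"))
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  df2 <- length(y) - fit1$rank
  if (df2 <= 0 || rss1 <= 0)
    return(list(p_value = NA_real_, reason = "saturated"))
  f <- (rss0 - rss1) / (rss1 / df2)
  list(p_value = pf(f, 1, df2, lower.tail = FALSE), reason = NA_character_)
}

#' Covariate-adjusted association test for one drug-CFE pair
#'
#' Ordinary least squares of ln IC50 on the covariates plus the binary CFE
#' status; the reported p-value is the F-test of the CFE term added last.
#' Complete cases only. In the pan-cancer setting the covariates are cancer
#' type and MSI status; in a cancer-specific setting, MSI only.
#'
#' @param response numeric vector of ln IC50 values.
#' @param cfe binary vector (0/1) of CFE status, same length.
#' @param covariates optional data frame of factors (e.g. cancer type, MSI),
#'   same length; constant columns are dropped automatically.
#' @param min_group minimum number of positive and of negative complete
#'   cases (default 3, the smallest size with a defined group variance).
#' @return list with `p_value`, `n_pos`, `n_neg` and `reason` (`NA` for a
#'   performed test; `"group_size"` for a skipped one; `"confounded"` when
#'   the CFE term is collinear with the covariates and dropped).
#' @export
fit_association <- function(response, cfe, covariates = NULL, min_group = 3) {
  stopifnot(length(response) == length(cfe))
  keep <- !is.na(response) & !is.na(cfe)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(response))
    keep <- keep & complete.cases(covariates)
  }
  y <- response[keep]; x <- cfe[keep]
  n_pos <- sum(x == 1); n_neg <- sum(x == 0)
  if (n_pos < min_group || n_neg < min_group)
    return(list(p_value = NA_real_, n_pos = n_pos, n_neg = n_neg,
                reason = "group_size"))
  cov_k <- usable_covariates(covariates[keep, , drop = FALSE])
  Z <- if (is.null(cov_k)) matrix(1, length(y), 1,
                                  dimnames = list(NULL, "(Intercept)"))
       else model.matrix(~ ., data = as.data.frame(lapply(cov_k, factor)))
  res <- anova_term_p(y, x, Z)
  c(res[c("p_value", "reason")], list(n_pos = n_pos, n_neg = n_neg))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values (q-values) with monotonicity enforcement, as
#' used to control the FDR across all tests of one association scan.
#'
#' @param p_values numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Drug-CFE association scan with effect-size gating
#'
#' Tests every testable (drug, CFE) pair with [fit_association()], controls
#' the FDR across all tests of the scan with [bh_fdr()], and gates hits the
#' way large pharmacogenomic screens report them: `significant` when
#' `p < p_thr` and `FDR < fdr_thr` (defaults 1e-3 and 25%); `large_effect`
#' when additionally both Glass deltas exceed `delta_thr` (default 1).
#' Direction is `sensitizing` when carriers have the lower mean ln IC50.
#'
#' Pan-cancer scans adjust for cancer type and MSI status; cancer-specific
#' scans restrict to one cancer type (more than 15 cell lines required) and
#' adjust for MSI only. Tests are enumerated in sorted (drug, CFE) order, so
#' results do not depend on input row or column ordering.
#'
#' @param responses a [drug_response()].
#' @param alterations an [alteration_matrix()] of cell lines.
#' @param mode `"pan_cancer"` or `"cancer_specific"`.
#' @param cancer_type cancer-type label, required for cancer-specific scans.
#' @param p_thr,fdr_thr,delta_thr significance and effect-size gates.
#' @param min_group minimum carriers and non-carriers per test.
#' @return an `association_table`: data frame with one row per performed test
#'   (`drug_id`, `cfe_id`, `analysis`, `n_pos`, `n_neg`, `delta_mean`,
#'   `cohens_d`, `glass_pos`, `glass_neg`, `p_value`, `fdr`, `significant`,
#'   `large_effect`, `direction`) and attributes `thresholds` and `skipped`
#'   (reason counts for untested pairs).
#' @export
run_scan <- function(responses, alterations,
                     mode = c("pan_cancer", "cancer_specific"),
                     cancer_type = NULL, p_thr = 1e-3, fdr_thr = 0.25,
                     delta_thr = 1, min_group = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(responses, "drug_response"),
            inherits(alterations, "alteration_matrix"))
  samples <- sort(intersect(rownames(responses$ic50),
                            rownames(alterations$values)))
  ann <- alterations$annotations[match(samples, alterations$annotations$sample_id), ]
  if (mode == "cancer_specific") {
    if (is.null(cancer_type)) stop("cancer_type required for a cancer-specific scan")
    samples <- samples[ann$cancer_type == cancer_type]
    if (length(samples) <= 15)
      stop("cancer-specific scans require more than 15 cell lines")
    ann <- ann[ann$cancer_type == cancer_type, ]
    covariates <- data.frame(msi = ann$msi)
    analysis <- paste0("cancer_specific:", cancer_type)
  } else {
    covariates <- data.frame(cancer_type = ann$cancer_type, msi = ann$msi)
    analysis <- "pan_cancer"
  }
  ic50 <- responses$ic50[samples, , drop = FALSE]
  X <- alterations$values[samples, , drop = FALSE]
  drugs <- sort(colnames(ic50)); cfes <- sort(colnames(X))
  cov_u <- usable_covariates(covariates)
  Zfull <- if (is.null(cov_u)) matrix(1, length(samples), 1)
           else model.matrix(~ ., data = as.data.frame(lapply(cov_u, factor)))
  rows <- vector("list", length(drugs) * length(cfes))
  skipped <- c(group_size = 0L, confounded = 0L, saturated = 0L)
  k <- 0L
  for (d in drugs) {
    y_all <- ic50[, d]
    keep_d <- !is.na(y_all)
    Zd <- Zfull[keep_d, , drop = FALSE]
    fit0_d <- if (sum(keep_d) > ncol(Zd)) lm.fit(Zd, y_all[keep_d]) else NULL
    for (cf in cfes) {
      x_all <- X[, cf]
      keep <- keep_d & !is.na(x_all)
      y <- y_all[keep]; x <- x_all[keep]
      n_pos <- sum(x == 1); n_neg <- sum(x == 0)
      if (n_pos < min_group || n_neg < min_group) {
        skipped["group_size"] <- skipped["group_size"] + 1L
        next
      }
      res <- if (identical(keep, keep_d) && !is.null(fit0_d))
        anova_term_p(y, x, Zd, fit0_d)
      else anova_term_p(y, x, Zfull[keep, , drop = FALSE])
      if (is.na(res$p_value)) {
        skipped[res$reason] <- skipped[res$reason] + 1L
        next
      }
      es <- effect_sizes(y[x == 1], y[x == 0])
      delta <- mean(y[x == 1]) - mean(y[x == 0])
      k <- k + 1L
      rows[[k]] <- data.frame(
        drug_id = d, cfe_id = cf, analysis = analysis,
        n_pos = n_pos, n_neg = n_neg, delta_mean = delta,
        cohens_d = es$cohens_d, glass_pos = es$glass_pos,
        glass_neg = es$glass_neg, p_value = res$p_value)
    }
  }
  tab <- if (k > 0) do.call(rbind, rows[seq_len(k)]) else
    data.frame(drug_id = character(), cfe_id = character(),
               analysis = character(), n_pos = integer(), n_neg = integer(),
               delta_mean = numeric(), cohens_d = numeric(),
               glass_pos = numeric(), glass_neg = numeric(),
               p_value = numeric())
  tab$fdr <- bh_fdr(tab$p_value)
  tab$significant <- !is.na(tab$p_value) & tab$p_value < p_thr &
    tab$fdr < fdr_thr
  tab$large_effect <- tab$significant &
    !is.na(tab$glass_pos) & !is.na(tab$glass_neg) &
    tab$glass_pos > delta_thr & tab$glass_neg > delta_thr
  tab$direction <- ifelse(tab$delta_mean < 0, "sensitizing", "resistance")
  rownames(tab) <- NULL
  structure(tab, class = c("association_table", "data.frame"),
            thresholds = list(p_thr = p_thr, fdr_thr = fdr_thr,
                              delta_thr = delta_thr, min_group = min_group,
                              mode = mode, cancer_type = cancer_type),
            skipped = skipped)
}

#' Downsampling experiment for an association scan
#'
#' Reruns the scan on random subsets of cell lines and reports the retention
#' of the full-cohort significant and large-effect hits, plus the mean
#' absolute shift in effect size (Cohen's d) of the retained hits — the
#' standard way to quantify how cohort size drives discovery power.
#'
#' @param responses,alterations as in [run_scan()].
#' @param sizes integer vector of subset sizes (all below the full cohort);
#'   defaults to the conventional 500/300/150/60 ladder, truncated to the
#'   cohort at hand.
#' @param reps subsets per size.
#' @param seed integer seed fixing the subsets.
#' @param ... passed to [run_scan()].
#' @return data frame with one row per (size, rep): hit counts, retention
#'   fractions in `[0, 1]`, and `mean_abs_d_change` over retained hits. The
#'   full-cohort `association_table` is attached as attribute `full_scan`.
#' @export
downsample_experiment <- function(responses, alterations,
                                  sizes = c(500, 300, 150, 60), reps = 5,
                                  seed = 1, ...) {
  samples <- intersect(rownames(responses$ic50), rownames(alterations$values))
  if (any(sizes > length(samples)))
    stop("downsampling sizes must not exceed the cohort size (",
         length(samples), ")")
  full <- run_scan(responses, alterations, ...)
  key <- function(t) paste(t$drug_id, t$cfe_id, sep = "::")
  full_sig <- key(full)[full$significant]
  full_large <- key(full)[full$large_effect]
  full_d <- setNames(full$cohens_d, key(full))
  out <- list()
  with_seed(seed, {
    for (sz in sizes) for (r in seq_len(reps)) {
      sub <- sample(samples, sz)
      sub_resp <- drug_response(responses$ic50[sub, , drop = FALSE],
                                responses$max_conc)
      scan <- run_scan(sub_resp, subset_samples(alterations, sub), ...)
      sig <- key(scan)[scan$significant]
      large <- key(scan)[scan$large_effect]
      kept <- intersect(full_sig, sig)
      d_change <- if (length(kept) > 0)
        mean(abs(setNames(scan$cohens_d, key(scan))[kept] - full_d[kept]))
      else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        size = sz, rep = r, n_sig_full = length(full_sig),
        n_large_full = length(full_large), n_sig = length(sig),
        retention_sig = if (length(full_sig) > 0)
          length(kept) / length(full_sig) else NA_real_,
        retention_large = if (length(full_large) > 0)
          length(intersect(full_large, large)) / length(full_large)
        else NA_real_,
        mean_abs_d_change = d_change)
    }
  })
  res <- do.call(rbind, out)
  attr(res, "full_scan") <- full
  res
}

#' Cross-study validation of association results
#'
#' Compares two association tables over their shared (drug, CFE) pairs: the
#' Pearson correlation of signed significance (`-log10(p)` times the sign of
#' the mean ln-IC50 difference), and the fraction of table-A significant hits
#' that validate in table B (`p < 0.05` with the same direction), split by
#' sensitizing versus resistance hits, with a Fisher exact test on the
#' validated-by-direction table.
#'
#' @param table_a,table_b `association_table` objects sharing at least 10
#'   (drug, CFE) pairs.
#' @return list with `pearson_signed_logp`, `validation_rate_sensitizing`,
#'   `validation_rate_resistance`, `fet_p`, `n_shared` and a per-hit
#'   `detail` data frame.
#' @export
cross_study_validate <- function(table_a, table_b) {
  key <- function(t) paste(t$drug_id, t$cfe_id, sep = "::")
  ka <- key(table_a); kb <- key(table_b)
  shared <- intersect(ka, kb)
  if (length(shared) < 10)
    stop("tables must share at least 10 (drug, CFE) pairs")
  a <- table_a[match(shared, ka), ]; b <- table_b[match(shared, kb), ]
  signed <- function(t) -log10(pmax(t$p_value, 1e-300)) * sign(t$delta_mean)
  r <- cor(signed(a), signed(b), use = "complete.obs")
  hits <- which(a$significant)
  validated <- b$p_value[hits] < 0.05 & b$direction[hits] == a$direction[hits]
  dir_a <- a$direction[hits]
  rate <- function(d) if (sum(dir_a == d) > 0)
    mean(validated[dir_a == d]) else NA_real_
  fet_p <- if (length(hits) > 1 && length(unique(dir_a)) == 2 &&
                 length(unique(validated)) == 2)
    fisher.test(table(validated, dir_a))$p.value else NA_real_
  list(pearson_signed_logp = r,
       validation_rate_sensitizing = rate("sensitizing"),
       validation_rate_resistance = rate("resistance"),
       fet_p = fet_p, n_shared = length(shared),
       detail = data.frame(pair = shared[hits], direction = dir_a,
                           p_b = b$p_value[hits], validated = validated))
}
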