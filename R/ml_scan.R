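#' Assemble molecular feature views
#'
#' Splits an alteration matrix into its CFE-class views (CG mutations,
#' RACS copy-number segments, iCpG methylation calls), and adds optional
#' numeric expression and one-hot tissue views — the building blocks of the
#' data-type-combination scan.
#'
#' @param alterations an [alteration_matrix()] of cell lines.
#' @param catalog the governing [cfe_catalog()] (maps CFE id to class).
#' @param expression optional numeric matrix, samples x genes.
#' @return named list of numeric view matrices sharing row (sample) names:
#'   up to `CG`, `RACS`, `iCpG`, `expression`, `tissue`.
#' @export
feature_views <- function(alterations, catalog, expression = NULL) {
  stopifnot(inherits(alterations, "alteration_matrix"),
            inherits(catalog, "cfe_catalog"))
  cls <- setNames(catalog$cfes$cfe_class, catalog$cfes$cfe_id)
  X <- alterations$values
  views <- list()
  pick <- function(classes) {
    ids <- colnames(X)[cls[colnames(X)] %in% classes]
    if (length(ids) > 0) X[, ids, drop = FALSE] else NULL
  }
  views$CG <- pick(c("CG", "fusion"))
  views$RACS <- pick(c("RACS_amp", "RACS_del"))
  views$iCpG <- pick("iCpG")
  if (!is.null(expression)) {
    stopifnot(identical(rownames(expression), rownames(X)))
    views$expression <- expression
  }
  tissue <- factor(alterations$annotations$cancer_type)
  oh <- model.matrix(~ tissue - 1)
  rownames(oh) <- rownames(X)
  colnames(oh) <- levels(tissue)
  views$tissue <- oh
  views[!vapply(views, is.null, logical(1))]
}

#' Concatenate a combination of views into one design matrix
#'
#' Binary and one-hot views pass through unchanged; the expression view is
#' standardized per feature (mean 0, sd 1; constant features dropped).
#'
#' @param views named list of view matrices with aligned sample rows.
#' @param combination character vector of view names to include (non-empty).
#' @return numeric design matrix, samples x concatenated features.
#' @export
build_feature_views <- function(views, combination) {
  stopifnot(length(combination) >= 1, all(combination %in% names(views)))
  rn <- rownames(views[[combination[1]]])
  mats <- lapply(combination, function(v) {
    m <- views[[v]]
    stopifnot(identical(rownames(m), rn))
    if (v == "expression") {
      keep <- apply(m, 2, sd) > 0
      m <- scale(m[, keep, drop = FALSE])
    }
    colnames(m) <- paste(v, colnames(m), sep = ".")
    m
  })
  do.call(cbind, mats)
}

#' Out-of-fold predictive performance of one drug-response model
#'
#' Nested cross-validation: the outer folds provide strictly held-out
#' predictions, the inner level tunes hyperparameters (the elastic-net
#' penalty by inner CV; the random-forest `mtry` by out-of-bag error).
#' Performance is the Pearson correlation of observed versus out-of-fold
#' predicted ln IC50 — the standard score for comparing molecular data
#' types. Each fold's predictions are centered on its training mean before
#' pooling: an uninformative model then contributes a constant (scored
#' `r = 0`) instead of the training-fold means, whose anticorrelation with
#' the held-out means would otherwise bias null correlations negative.
#'
#' @param X numeric design matrix (samples x features).
#' @param y ln IC50 vector; at least 40 complete cases required.
#' @param method `"penalized_linear"` (elastic net, alpha = 0.5) or
#'   `"tree_ensemble"` (random forest).
#' @param folds number of outer folds (default 5).
#' @param seed integer seed fixing all folds.
#' @return list with `r` (Pearson of observed vs out-of-fold predictions; 0
#'   when the predictions are constant, `NA` when `y` is constant), `n`,
#'   `method` and the `predictions` vector.
#' @export
fit_predictor <- function(X, y, method = c("penalized_linear", "tree_ensemble"),
                          folds = 5, seed = 1) {
  method <- match.arg(method)
  keep <- !is.na(y) & complete.cases(X)
  X <- as.matrix(X[keep, , drop = FALSE]); y <- y[keep]
  n <- length(y)
  if (n < 40) stop("at least 40 complete-case samples are required")
  if (sd(y) == 0)
    return(list(r = NA_real_, n = n, method = method, predictions = NULL))
  pred <- rep(NA_real_, n)
  with_seed(seed, {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (method == "penalized_linear") {
        inner_id <- sample(rep_len(seq_len(5), sum(tr)))
        fit <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = 0.5,
                                 foldid = inner_id)
        pred[!tr] <- as.numeric(
          predict(fit, X[!tr, , drop = FALSE], s = "lambda.min")) - mean(y[tr])
      } else {
        mtry_grid <- unique(pmax(1, c(floor(sqrt(ncol(X))), floor(ncol(X) / 3))))
        oob <- vapply(mtry_grid, function(mt) {
          ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                         num.trees = 300, mtry = mt,
                         seed = seed + f)$prediction.error
        }, numeric(1))
        fit <- ranger::ranger(x = X[tr, , drop = FALSE], y = y[tr],
                              num.trees = 300,
                              mtry = mtry_grid[which.min(oob)],
                              seed = seed + f)
        pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])$predictions -
          mean(y[tr])
      }
    }
  })
  r <- if (sd(pred) == 0) 0 else cor(y, pred)
  list(r = r, n = n, method = method, predictions = pred)
}

#' Scan all combinations of molecular data types for one drug
#'
#' Fits one predictor per non-empty combination of the available views
#' (singles, pairs, triples, ..., all) and reports the out-of-fold Pearson
#' correlation of each. Pan-cancer scans may include the tissue view;
#' cancer-specific scans exclude it.
#'
#' @param y ln IC50 vector aligned with the view rows.
#' @param views named list of view matrices (see [feature_views()]).
#' @param method passed to [fit_predictor()].
#' @param mode `"pan_cancer"` (tissue allowed) or `"cancer_specific"`
#'   (tissue dropped).
#' @param folds,seed passed to [fit_predictor()].
#' @return data frame with one row per combination: `combination`
#'   (`+`-joined view names), `n_views`, `r`, `n`.
#' @export
scan_combinations <- function(y, views, method = "penalized_linear",
                              mode = c("pan_cancer", "cancer_specific"),
                              folds = 5, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "cancer_specific") views$tissue <- NULL
  nm <- sort(names(views))
  stopifnot(length(nm) >= 1)
  combos <- unlist(lapply(seq_along(nm), function(k)
    combn(nm, k, simplify = FALSE)), recursive = FALSE)
  out <- lapply(combos, function(cb) {
    X <- build_feature_views(views, cb)
    fit <- fit_predictor(X, y, method = method, folds = folds, seed = seed)
    data.frame(combination = paste(cb, collapse = "+"),
               n_views = length(cb), r = fit$r, n = fit$n)
  })
  res <- do.call(rbind, out)
  res$mode <- mode
  res$method <- method
  res
}

#' Derive the predictiveness threshold from a mixture of model scores
#'
#' Fits a two-component Gaussian mixture to the Pearson correlations of all
#' built models, treats the higher-mean component as the informative one,
#' and returns the smallest correlation at which the posterior odds of
#' being informative reach `ratio` (default 9, i.e. 9:1) — taking the first
#' sustained crossing on a dense grid so a heavy-tailed null cannot produce
#' a spurious low-end threshold.
#'
#' @param r_values numeric vector of model correlations (at least 50).
#' @param ratio required informative : non-informative posterior odds.
#' @return the threshold correlation; `Inf` with a warning when the mixture
#'   collapses (components indistinguishable) or the odds never reach
#'   `ratio`. Attributes `means`, `sds`, `weights` expose the fit.
#' @export
derive_predictive_threshold <- function(r_values, ratio = 9) {
  r_values <- r_values[!is.na(r_values)]
  if (length(r_values) < 50) stop("at least 50 model scores are required")
  fit <- tryCatch(
    mclust::Mclust(r_values, G = 1:2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  collapse <- function(msg) {
    warning("mixture collapse: ", msg)
    structure(Inf, means = NULL, sds = NULL, weights = NULL)
  }
  if (is.null(fit)) return(collapse("fit failed"))
  if (fit$G < 2) return(collapse("a single component is BIC-preferred"))
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, 2)
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]; w <- w[ord]
  if ((mu[2] - mu[1]) < 0.5 * max(sig) || min(w) < 0.01)
    return(collapse("components indistinguishable"))
  grid <- seq(min(r_values), max(max(r_values), mu[2] + 3 * sig[2]),
              length.out = 4001)
  odds <- (w[2] * dnorm(grid, mu[2], sig[2])) /
    (w[1] * dnorm(grid, mu[1], sig[1]))
  sustained <- rev(cumprod(rev(odds >= ratio))) > 0
  if (!any(sustained)) return(collapse("odds never reach the ratio"))
  structure(grid[which(sustained)[1]], means = mu, sds = sig, weights = w)
}

#' Select lead models from a combination scan
#'
#' A model is `predictive` when its out-of-fold correlation reaches the
#' mode's threshold; the lead model of a drug is its best-performing
#' predictive model, ties going to the combination with fewer data types,
#' then lexicographic order. The summary counts lead models per data-type
#' combination — the basis for asking which molecular layers drive
#' predictability.
#'
#' @param performances data frame of scan rows (from [scan_combinations()],
#'   possibly concatenated over drugs) with columns `drug_id`,
#'   `combination`, `n_views`, `r`, `mode`.
#' @param threshold_pan,threshold_specific predictiveness thresholds
#'   (defaults 0.21 and 0.25; [derive_predictive_threshold()] recomputes
#'   them from scratch).
#' @return list with `leads` (one row per (drug, mode) with a predictive
#'   model), `summary` (lead counts per combination and mode) and
#'   `n_without` (drugs with no predictive model).
#' @export
select_lead_models <- function(performances, threshold_pan = 0.21,
                               threshold_specific = 0.25) {
  stopifnot(all(c("drug_id", "combination", "n_views", "r", "mode") %in%
                  names(performances)))
  thr <- ifelse(performances$mode == "pan_cancer",
                threshold_pan, threshold_specific)
  performances$predictive <- !is.na(performances$r) & performances$r >= thr
  leads <- list(); n_without <- 0L
  for (grp in split(performances,
                    paste(performances$drug_id, performances$mode))) {
    cand <- grp[grp$predictive, , drop = FALSE]
    if (nrow(cand) == 0) { n_without <- n_without + 1L; next }
    cand <- cand[order(-cand$r, cand$n_views, cand$combination), ]
    leads[[length(leads) + 1L]] <- cand[1, ]
  }
  leads <- if (length(leads) > 0) do.call(rbind, leads) else
    performances[0, ]
  summary <- if (nrow(leads) > 0)
    aggregate(list(n_lead = leads$drug_id),
              by = list(mode = leads$mode, combination = leads$combination),
              FUN = length)
  else data.frame(mode = character(), combination = character(),
                  n_lead = integer())
  list(leads = leads, summary = summary, n_without = n_without)
}
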