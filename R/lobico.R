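#' Boolean formulas over binary genomic features
#'
#' A `logic_formula` is a two-level AND/OR combination of CFE literals, the
#' hypothesis class of the logic-model inference: disjunctive normal form
#' (DNF, an OR of AND-clauses) or conjunctive normal form (CNF, an AND of
#' OR-clauses). A literal is a CFE id, optionally negated with a `"!"`
#' prefix (e.g. `"!FAT1_del"` for lack of a deletion).
#'
#' @param clauses list of character vectors; each vector is one clause of
#'   literals. An empty clause list is the null formula: it predicts no
#'   sample sensitive under DNF (and every sample under CNF).
#' @param form `"DNF"` or `"CNF"`.
#' @return an object of class `logic_formula`.
#' @examples
#' logic_formula(list("KRAS_mut", "BRAF_mut"))              # KRAS | BRAF
#' logic_formula(list(c("TP53_mut", "!FAT1_del")))          # TP53 & !FAT1
#' @export
logic_formula <- function(clauses, form = c("DNF", "CNF")) {
  form <- match.arg(form)
  stopifnot(is.list(clauses),
            all(vapply(clauses, is.character, logical(1))),
            all(lengths(clauses) >= 1 | length(clauses) == 0))
  structure(list(clauses = clauses, form = form), class = "logic_formula")
}

#' @export
format.logic_formula <- function(x, ...) {
  if (length(x$clauses) == 0)
    return(if (x$form == "DNF") "<null: all resistant>" else "<null: all sensitive>")
  inner <- if (x$form == "DNF") " & " else " | "
  outer <- if (x$form == "DNF") " | " else " & "
  cl <- vapply(x$clauses, function(l) {
    s <- paste(l, collapse = inner)
    if (length(l) > 1) paste0("(", s, ")") else s
  }, "")
  paste(cl, collapse = outer)
}

#' @export
print.logic_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Features referenced by a logic formula
#' @param formula a [logic_formula()] (or a `logic_model`).
#' @return character vector of distinct CFE ids.
#' @export
formula_features <- function(formula) {
  if (inherits(formula, "logic_model")) formula <- formula$formula
  unique(sub("^!", "", unlist(formula$clauses)))
}

#' Evaluate a logic formula on a binary feature matrix
#'
#' DNF: a sample is predicted sensitive when any clause has all its literals
#' satisfied; CNF dually. Negated literals invert the feature bit. A sample
#' with a missing value in any referenced feature gets `NA` (excluded from
#' metrics downstream).
#'
#' @param model a [logic_formula()] or a `logic_model`.
#' @param features binary matrix (samples x features, columns named by CFE
#'   id) or an [alteration_matrix()]. All referenced features must be
#'   present.
#' @return logical vector of predicted sensitivity, one entry per sample.
#' @export
evaluate_formula <- function(model, features) {
  if (inherits(model, "logic_model")) model <- model$formula
  stopifnot(inherits(model, "logic_formula"))
  if (inherits(features, "alteration_matrix")) features <- features$values
  feats <- formula_features(model)
  missing_f <- setdiff(feats, colnames(features))
  if (length(missing_f) > 0)
    stop("features absent from matrix: ", paste(missing_f, collapse = ", "))
  n <- nrow(features)
  if (length(model$clauses) == 0)
    return(setNames(rep(model$form == "CNF", n), rownames(features)))
  clause_val <- vapply(model$clauses, function(cl) {
    neg <- startsWith(cl, "!")
    v <- features[, sub("^!", "", cl), drop = FALSE]
    v[, neg] <- 1 - v[, neg, drop = FALSE]
    if (model$form == "DNF") rowSums(v) == length(cl) else rowSums(v) > 0
  }, logical(n))
  clause_val <- matrix(clause_val, nrow = n)
  out <- if (model$form == "DNF") rowSums(clause_val) > 0
         else rowSums(clause_val) == length(model$clauses)
  out[rowSums(is.na(clause_val)) > 0] <- NA
  setNames(out, rownames(features))
}

#' Binarize IC50s and derive continuous sample weights
#'
#' Cell lines are labeled sensitive when their ln IC50 is at or below the
#' binarization threshold theta and resistant otherwise. Each sample's
#' weight is proportional to its distance `|ln IC50 - theta|` from the
#' threshold — clearly sensitive or clearly resistant lines count more in
#' the optimization than borderline ones — normalized so that each class's
#' weights sum to 0.5 (a balanced objective; total weight 1).
#'
#' @param ic50s numeric vector of ln IC50 values (no `NA`).
#' @param theta binarization threshold on the ln IC50 scale.
#' @return list with `labels` (logical, `TRUE` = sensitive) and `weights`
#'   (numeric, non-negative; a sample exactly at theta gets weight 0).
#' @export
binarize_and_weight <- function(ic50s, theta) {
  stopifnot(!any(is.na(ic50s)))
  labels <- ic50s <= theta
  if (all(labels) || !any(labels))
    stop("both sensitive and resistant classes must be non-empty")
  weights <- half_weights(ic50s, theta, rep(TRUE, length(ic50s)))
  list(labels = setNames(labels, names(ic50s)),
       weights = setNames(weights, names(ic50s)))
}

# |ic50 - theta| weights, class sums 0.5 within `subset`, zero outside;
# if the subset holds a single class, its weights sum to 1
half_weights <- function(ic50s, theta, subset) {
  w <- abs(ic50s - theta)
  w[!subset] <- 0
  sens <- ic50s <= theta
  both <- any(sens & subset) && any(!sens & subset)
  for (cls in list(sens & subset, !sens & subset)) {
    s <- sum(w[cls])
    if (s > 0) w[cls] <- w[cls] / s * (if (both) 0.5 else 1)
  }
  w
}

#' The eight default model complexities
#'
#' The symmetric family of two-level AND/OR models with up to four CFE
#' inputs used for complexity selection: a single literal, pure AND models
#' of up to 2-4 literals, pure OR models of up to 2-4 literals, and the
#' 2x2 OR-of-ANDs (DNF). Each complexity is nested in the larger ones of
#' its family ("up to" semantics), so the optimal training objective is
#' non-increasing with complexity.
#'
#' @return list of complexity descriptors `list(k, m, form, label)`.
#' @export
lobico_complexities <- function() {
  list(list(k = 1, m = 1, form = "DNF", label = "single"),
       list(k = 1, m = 2, form = "DNF", label = "and2"),
       list(k = 2, m = 1, form = "DNF", label = "or2"),
       list(k = 1, m = 3, form = "DNF", label = "and3"),
       list(k = 3, m = 1, form = "DNF", label = "or3"),
       list(k = 1, m = 4, form = "DNF", label = "and4"),
       list(k = 4, m = 1, form = "DNF", label = "or4"),
       list(k = 2, m = 2, form = "DNF", label = "dnf2x2"))
}

# ---- formula library -------------------------------------------------------
# Enumerates, once per feature set, the prediction vector of every candidate
# formula of the requested complexities, so that CV folds and permutations
# reduce to two crossproducts against a fixed matrix.
#
# Candidate classes ("up to" semantics; literals within a clause use distinct
# features, negation allowed):
#   and-clauses of size 1..m   -> complexity (1, m) DNF  [== CNF (m, 1)]
#   or-of-literals of size 2..k + single literals -> (k, 1) DNF [== CNF (1, k)]
#   pairs of and-clauses (<=2 literals)  -> (2, 2) DNF
#   pairs of or-clauses  (<=2 literals)  -> (2, 2) CNF
logic_library <- function(X, complexities = lobico_complexities()) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (any(is.na(X))) stop("logic-model features must be complete (no NA)")
  nf <- ncol(X)
  ids <- colnames(X)
  L <- cbind(X, 1 - X)
  storage.mode(L) <- "double"
  lit_names <- c(ids, paste0("!", ids))
  lit_feat <- rep(seq_len(nf), 2)

  and_sizes <- integer(0); or_sizes <- integer(0)
  want_dnf22 <- FALSE; want_cnf22 <- FALSE
  for (cp in complexities) {
    k <- cp$k; m <- cp$m
    dnf <- identical(cp$form, "DNF")
    if (k == 1 && m == 1) and_sizes <- c(and_sizes, 1)
    else if (k == 1) { if (dnf) and_sizes <- c(and_sizes, 1:m)
                       else { or_sizes <- c(or_sizes, 2:m); and_sizes <- c(and_sizes, 1) } }
    else if (m == 1) { if (dnf) { or_sizes <- c(or_sizes, 2:k); and_sizes <- c(and_sizes, 1) }
                       else and_sizes <- c(and_sizes, 1:k) }
    else if (k == 2 && m == 2) {
      and_sizes <- c(and_sizes, 1:2); or_sizes <- c(or_sizes, 2)
      if (dnf) want_dnf22 <- TRUE else want_cnf22 <- TRUE
    } else stop("unsupported complexity: K=", k, ", M=", m)
  }
  and_sizes <- sort(unique(and_sizes)); or_sizes <- sort(unique(or_sizes))
  if (max(c(and_sizes, or_sizes, 0)) > nf)
    and_sizes <- and_sizes[and_sizes <= nf]
  or_sizes <- or_sizes[or_sizes <= 2 * nf]

  preds <- list(); defs <- list(); id_str <- list(); nfeat <- list()
  group <- list(); gsize <- list()
  add <- function(P, def, id, nft, grp, sz) {
    i <- length(preds) + 1L
    preds[[i]] <<- P; defs[[i]] <<- def; id_str[[i]] <<- id
    nfeat[[i]] <<- nft; group[[i]] <<- rep(grp, length(id))
    gsize[[i]] <<- sz
  }
  clause_block <- function(s, type) {
    # all clauses of exactly s literals over distinct features;
    # type "and": product of literals, "or": clipped sum
    combos <- combn(nf, s)
    signs <- as.matrix(expand.grid(rep(list(c(0L, 1L)), s)))
    P_all <- list(); def_all <- list(); id_all <- list()
    for (g in seq_len(nrow(signs))) {
      li <- combos + nf * signs[g, ]
      if (s == 1) li <- matrix(li, nrow = 1)
      P <- L[, li[1, ], drop = FALSE]
      if (s > 1) for (r in 2:s) {
        P <- if (type == "and") P * L[, li[r, ], drop = FALSE]
             else P + L[, li[r, ], drop = FALSE]
      }
      if (type == "or" && s > 1) P <- pmin(P, 1)
      sep <- if (type == "and") "&" else "|"
      id <- apply(li, 2, function(j) paste(lit_names[j], collapse = sep))
      P_all[[g]] <- P
      def_all[[g]] <- lapply(seq_len(ncol(li)), function(j) li[, j])
      id_all[[g]] <- id
    }
    list(pred = do.call(cbind, P_all), def = do.call(c, def_all),
         id = do.call(c, id_all))
  }
  and_blocks <- list()
  for (s in and_sizes) {
    b <- clause_block(s, "and")
    and_blocks[[as.character(s)]] <- b
    add(b$pred, lapply(b$def, list), b$id,
        rep(s, length(b$id)), "and", rep(s, length(b$id)))
  }
  for (s in or_sizes) {
    combos <- combn(2 * nf, s)
    P <- L[, combos[1, ], drop = FALSE]
    for (r in 2:s) P <- P + L[, combos[r, ], drop = FALSE]
    P <- pmin(P, 1)
    id <- apply(combos, 2, function(j) paste(lit_names[j], collapse = "|"))
    nft <- apply(combos, 2, function(j) length(unique(lit_feat[j])))
    add(P, lapply(seq_len(ncol(combos)),
                  function(j) as.list(combos[, j])),
        id, nft, "or", rep(s, ncol(combos)))
  }
  pair_block <- function(type) {
    # pairs of <=2-literal clauses; for DNF the clauses are ANDs combined by
    # OR, for CNF the clauses are ORs combined by AND
    cl <- if (type == "dnf") {
      list(pred = cbind(and_blocks[["1"]]$pred, and_blocks[["2"]]$pred),
           def = c(and_blocks[["1"]]$def, and_blocks[["2"]]$def),
           id = c(and_blocks[["1"]]$id, and_blocks[["2"]]$id))
    } else {
      b1 <- and_blocks[["1"]]; b2 <- clause_block(2, "or")
      list(pred = cbind(b1$pred, b2$pred), def = c(b1$def, b2$def),
           id = c(b1$id, b2$id))
    }
    nc <- length(cl$id)
    pr <- combn(nc, 2)
    A <- cl$pred[, pr[1, ], drop = FALSE]
    B <- cl$pred[, pr[2, ], drop = FALSE]
    P <- if (type == "dnf") A + B - A * B else A * B
    wrap <- function(x) ifelse(grepl("[&|]", x), paste0("(", x, ")"), x)
    sepo <- if (type == "dnf") " | " else " & "
    id <- paste(pmin(wrap(cl$id[pr[1, ]]), wrap(cl$id[pr[2, ]])),
                pmax(wrap(cl$id[pr[1, ]]), wrap(cl$id[pr[2, ]])), sep = sepo)
    def <- lapply(seq_len(ncol(pr)),
                  function(j) c(cl$def[[pr[1, j]]], cl$def[[pr[2, j]]]))
    nft <- vapply(def, function(d) length(unique(lit_feat[unlist(d)])),
                  integer(1))
    add(P, def, id, nft, type, rep(2L, length(id)))
  }
  if (want_dnf22 && nf >= 2) pair_block("dnf")
  if (want_cnf22 && nf >= 2) pair_block("cnf")

  pred <- do.call(cbind, preds)
  group <- unlist(group); gsize <- unlist(gsize)
  id_str <- unlist(id_str); nfeat <- unlist(nfeat)
  masks <- list()
  for (cp in complexities) {
    k <- cp$k; m <- cp$m
    dnf <- identical(cp$form, "DNF")
    sel <- if (k == 1 && m == 1) group == "and" & gsize == 1
      else if (k == 1 && dnf || m == 1 && !dnf)
        group == "and" & gsize <= max(k, m)
      else if (m == 1 && dnf || k == 1 && !dnf)
        (group == "and" & gsize == 1) | (group == "or" & gsize <= max(k, m))
      else if (dnf)
        (group == "and" & gsize <= 2) | (group == "or" & gsize == 2) |
          group == "dnf"
      else
        (group == "and" & gsize <= 2) | (group == "or" & gsize == 2) |
          group == "cnf"
    masks[[cp$label]] <- which(sel)
  }
  list(pred = pred, defs = defs_flat(defs), id = id_str, nfeat = nfeat,
       group = group, masks = masks, lit_names = lit_names,
       lit_feat = lit_feat, features = ids, n = nrow(X))
}

defs_flat <- function(defs) do.call(c, defs)

# reconstruct the logic_formula of library column j
column_formula <- function(lib, j, form_hint = "DNF") {
  def <- lib$defs[[j]]
  grp <- lib$group[j]
  lits <- function(idx) lib$lit_names[unlist(idx)]
  if (grp == "and") logic_formula(list(lits(def)), form = "DNF")
  else if (grp == "or") logic_formula(as.list(lits(def)), form = "DNF")
  else if (grp == "dnf") logic_formula(lapply(def, lits), form = "DNF")
  else logic_formula(lapply(def, lits), form = "CNF")
}

# weighted misclassification and specificity of every library column
lobico_objective <- function(lib, sens, weights, subset = NULL) {
  w <- weights
  e0 <- as.numeric(!sens)
  if (!is.null(subset)) { w[!subset] <- 0; e0[!subset] <- 0 }
  a <- w * sens; b <- w * !sens
  sc <- crossprod(lib$pred, cbind(err = b - a, fp = e0))
  n0 <- sum(e0)
  list(err = sum(a) + sc[, "err"],
       spec = if (n0 > 0) 1 - sc[, "fp"] / n0
              else rep(1, ncol(lib$pred)),
       total_w = sum(w), n0 = n0, w_sens = sum(a))
}

# argmin of the weighted objective within one complexity mask, subject to the
# specificity constraint; ties -> fewer distinct features, then lexicographic
select_best_column <- function(lib, label, obj, min_specificity) {
  idx <- lib$masks[[label]]
  feas <- idx[obj$spec[idx] >= min_specificity - 1e-9]
  if (length(feas) == 0) return(NULL)
  m <- min(obj$err[feas])
  cand <- feas[obj$err[feas] <= m + 1e-9]
  ord <- order(lib$nfeat[cand], lib$id[cand])
  cand[ord[1]]
}

#' Fit the optimal logic model of one complexity
#'
#' Exhaustively enumerates every AND/OR formula of the given complexity
#' (up to K clauses of up to M distinct-feature literals, negation allowed)
#' and returns one that minimizes the total weight of misclassified samples,
#' subject to a training specificity of at least `min_specificity`. Ties are
#' broken toward fewer distinct features, then lexicographically on the
#' formula string. When no formula satisfies the specificity constraint the
#' null model (predicting every line resistant) is returned, flagged
#' infeasible. With more than `prefilter` features, the search is restricted
#' to the top `prefilter` features ranked by single-feature weighted
#' accuracy.
#'
#' @param features binary matrix (samples x CFEs) or [alteration_matrix()];
#'   no missing values.
#' @param labels logical vector, `TRUE` = sensitive (from
#'   [binarize_and_weight()]).
#' @param weights per-sample weights (from [binarize_and_weight()]).
#' @param complexity a descriptor `list(k, m, form)` or numeric `c(k, m)`
#'   (DNF assumed).
#' @param min_specificity minimum training specificity (default 0.8).
#' @param prefilter maximum number of features searched exhaustively
#'   (default 12; exhaustive enumeration of the 2x2 class is quadratic in
#'   the clause count, so this bounds memory and time).
#' @return an object of class `logic_model`: list with `formula`
#'   ([logic_formula()]), `complexity`, `train_error` (weighted
#'   misclassification in `[0, 1]`), `precision`, `recall`, `specificity`
#'   (training), `feasible` and `threshold` (`NA` until set by a caller that
#'   knows the binarization).
#' @export
fit_logic_model <- function(features, labels, weights, complexity = c(1, 1),
                            min_specificity = 0.8, prefilter = 12) {
  if (inherits(features, "alteration_matrix")) features <- features$values
  if (is.numeric(complexity))
    complexity <- list(k = complexity[1], m = complexity[2], form = "DNF")
  complexity$label <- complexity$label %||%
    sprintf("K%dM%d_%s", complexity$k, complexity$m,
            complexity$form %||% "DNF")
  complexity$form <- complexity$form %||% "DNF"
  stopifnot(length(labels) == nrow(features),
            length(weights) == nrow(features), any(labels), any(!labels))
  keep <- prefilter_features(features, labels, weights, prefilter)
  lib <- logic_library(features[, keep, drop = FALSE], list(complexity))
  obj <- lobico_objective(lib, labels, weights)
  col <- select_best_column(lib, complexity$label, obj, min_specificity)
  build_logic_model(lib, col, obj, complexity, labels)
}

prefilter_features <- function(features, labels, weights, prefilter) {
  if (ncol(features) <= prefilter) return(colnames(features))
  a <- weights * labels; b <- weights * !labels
  err_pos <- sum(a) + crossprod(features, b - a)
  err_neg <- sum(a) + crossprod(1 - features, b - a)
  best <- pmin(err_pos, err_neg)
  colnames(features)[order(best, colnames(features))[seq_len(prefilter)]]
}

build_logic_model <- function(lib, col, obj, complexity, labels) {
  tw <- max(obj$total_w, .Machine$double.eps)
  if (is.null(col)) {
    # infeasible: null model predicts all resistant, misclassifying the
    # entire sensitive weight mass
    formula <- logic_formula(list(), form = "DNF")
    pred <- rep(FALSE, length(labels))
    train_error <- obj$w_sens / tw
    feasible <- FALSE
  } else {
    formula <- column_formula(lib, col)
    pred <- lib$pred[, col] > 0.5
    train_error <- unname(obj$err[col]) / tw
    feasible <- TRUE
  }
  met <- confusion_metrics(pred, labels)
  structure(list(formula = formula,
                 complexity = complexity$label, form = complexity$form,
                 train_error = train_error,
                 precision = met$precision, recall = met$recall,
                 specificity = met$specificity,
                 feasible = feasible, threshold = NA_real_),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat(sprintf("logic_model [%s]: %s\n", x$complexity, format(x$formula)))
  cat(sprintf("  train error %.3f | precision %.2f | recall %.2f | specificity %.2f%s\n",
              x$train_error, x$precision, x$recall, x$specificity,
              if (!x$feasible) " | INFEASIBLE (null model)" else ""))
  invisible(x)
}

confusion_metrics <- function(pred, labels) {
  ok <- !is.na(pred) & !is.na(labels)
  pred <- pred[ok]; labels <- labels[ok]
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  rt <- function(num, den) if (den > 0) num / den else NA_real_
  list(precision = rt(tp, tp + fp), recall = rt(tp, tp + fn),
       specificity = rt(tn, tn + fp), n_excluded = sum(!ok))
}

#' Precision, recall and specificity of a logic model
#'
#' Sensitive is the positive class: precision = TP / (TP + FP), recall =
#' TP / (TP + FN), specificity = TN / (TN + FP). Samples with missing
#' predictions are excluded; a zero denominator yields `NA`.
#'
#' @param model a `logic_model` or [logic_formula()].
#' @param features binary feature matrix or [alteration_matrix()].
#' @param labels logical vector, `TRUE` = sensitive.
#' @return list with `precision`, `recall`, `specificity`, `n_excluded`.
#' @export
model_metrics <- function(model, features, labels) {
  pred <- evaluate_formula(model, features)
  confusion_metrics(pred, labels)
}

# ---- cross-validation engine ----------------------------------------------
# Stratified folds, per-fold exhaustive fits at each complexity against a
# fixed formula library, held-out weighted misclassification. Weights are
# recomputed within each training and test subset (class sums 0.5 each).
lobico_engine <- function(lib, ic50s, theta, complexities, folds, repeats,
                          seed, min_specificity) {
  n <- length(ic50s)
  sens <- ic50s <= theta
  labels <- vapply(complexities, `[[`, "", "label")
  n_slots <- folds * repeats
  errs <- matrix(NA_real_, length(complexities), n_slots,
                 dimnames = list(labels, NULL))
  picks <- matrix(NA_integer_, length(complexities), n_slots,
                  dimnames = list(labels, NULL))
  run <- function() {
    for (r in seq_len(repeats)) {
      fold_id <- integer(n)
      for (cls in list(which(sens), which(!sens)))
        fold_id[sample(cls)] <- rep_len(seq_len(folds), length(cls))
      for (f in seq_len(folds)) {
        train <- fold_id != f
        test <- !train
        w_tr <- half_weights(ic50s, theta, train)
        w_te <- half_weights(ic50s, theta, test)
        obj <- lobico_objective(lib, sens, w_tr, subset = train)
        tw_te <- max(sum(w_te), .Machine$double.eps)
        slot <- (r - 1L) * folds + f
        for (ci in seq_along(complexities)) {
          col <- select_best_column(lib, labels[ci], obj, min_specificity)
          if (is.null(col)) {
            errs[labels[ci], slot] <<- sum(w_te[sens & test]) / tw_te
            picks[labels[ci], slot] <<- 0L
          } else {
            pred <- lib$pred[, col] > 0.5
            mis <- test & (pred != sens)
            errs[labels[ci], slot] <<- sum(w_te[mis]) / tw_te
            picks[labels[ci], slot] <<- col
          }
        }
      }
    }
  }
  if (is.null(seed)) run() else with_seed(seed, run())
  list(cv_table = errs, cv_means = rowMeans(errs), picks = picks)
}

#' Cross-validated logic-model inference for one drug
#'
#' The full logic-model workflow: binarize the ln IC50s at `theta`, weight
#' samples by their distance from the threshold, exhaustively fit the
#' optimal formula of each candidate complexity on stratified training
#' folds, select the complexity with the lowest mean held-out weighted
#' misclassification (ties go to the simpler model), and refit the selected
#' complexity on all samples.
#'
#' @param features binary matrix (samples x CFEs) or [alteration_matrix()].
#' @param ic50s named numeric vector of ln IC50 values aligned with the
#'   feature rows.
#' @param theta binarization threshold on the ln IC50 scale (conventionally
#'   the log maximum tested concentration).
#' @param complexities candidate complexities, default the eight of
#'   [lobico_complexities()].
#' @param folds number of CV folds (default 5, stratified on the
#'   sensitive/resistant labels).
#' @param repeats number of CV repeats averaged into the complexity
#'   selection.
#' @param seed integer seed fixing the folds.
#' @param min_specificity minimum training specificity for any returned
#'   formula (default 0.8).
#' @param prefilter maximum number of features enumerated exhaustively.
#' @param min_sensitive minimum number of sensitive cell lines required to
#'   attempt modeling (default 5); fewer raises an error (drug skipped).
#' @return an object of class `lobico_result`: list with `cv_error` (mean
#'   held-out error per complexity), `cv_table` (complexity x fold matrix),
#'   `selected` (complexity label), `model` (the refit `logic_model`, with
#'   `threshold` set), `fold_models` (features of the per-fold winning
#'   formulas, for feature importance), `n_sensitive`, and the `settings`
#'   needed to reproduce the run.
#' @export
lobico_cv <- function(features, ic50s, theta,
                      complexities = lobico_complexities(), folds = 5,
                      repeats = 1, seed = 1, min_specificity = 0.8,
                      prefilter = 12, min_sensitive = 5) {
  if (inherits(features, "alteration_matrix")) features <- features$values
  if (!is.null(names(ic50s))) {
    stopifnot(all(names(ic50s) %in% rownames(features)))
    features <- features[names(ic50s), , drop = FALSE]
  } else stopifnot(length(ic50s) == nrow(features))
  keep <- !is.na(ic50s)
  ic50s <- ic50s[keep]; features <- features[keep, , drop = FALSE]
  sens <- ic50s <= theta
  if (sum(sens) < min_sensitive)
    stop("fewer than ", min_sensitive, " sensitive cell lines; drug skipped")
  if (!any(!sens)) stop("no resistant cell lines; drug skipped")
  if (sum(sens) < folds)
    stop("cannot stratify ", folds, " folds with ", sum(sens),
         " sensitive lines; drug skipped")
  bw <- binarize_and_weight(ic50s, theta)
  keep_f <- prefilter_features(features, bw$labels, bw$weights, prefilter)
  lib <- logic_library(features[, keep_f, drop = FALSE], complexities)
  eng <- lobico_engine(lib, ic50s, theta, complexities, folds, repeats, seed,
                       min_specificity)
  sel_i <- which.min(eng$cv_means)  # first minimum: simplest on ties
  sel <- complexities[[sel_i]]
  obj <- lobico_objective(lib, bw$labels, bw$weights)
  col <- select_best_column(lib, sel$label, obj, min_specificity)
  model <- build_logic_model(lib, col, obj, sel, bw$labels)
  model$threshold <- theta
  fold_models <- apply(eng$picks, c(1, 2), function(col) {
    if (is.na(col) || col == 0L) list(character(0))
    else list(unique(lib$features[lib$lit_feat[unlist(lib$defs[[col]])]]))
  })
  structure(list(cv_error = eng$cv_means, cv_table = eng$cv_table,
                 selected = sel$label, model = model, theta = theta,
                 n_sensitive = sum(sens), n_resistant = sum(!sens),
                 fold_models = fold_models,
                 settings = list(complexities = complexities, folds = folds,
                                 repeats = repeats, seed = seed,
                                 min_specificity = min_specificity,
                                 prefilter = prefilter, features = keep_f)),
            class = "lobico_result")
}

#' @export
print.lobico_result <- function(x, ...) {
  cat(sprintf("lobico_result: selected '%s' (CV error %.3f), %d sensitive / %d resistant\n",
              x$selected, x$cv_error[x$selected], x$n_sensitive, x$n_resistant))
  print(x$model)
  invisible(x)
}

#' Permutation significance of a logic model
#'
#' Permutes the ln IC50 vector across samples, reruns the cross-validated
#' complexity selection on each permutation against the same formula
#' library, and compares the permuted minimal mean CV errors with the
#' observed one: `p = (1 + #\{perm error <= observed\}) / (n_perm + 1)`.
#'
#' @param result a [lobico_cv()] result.
#' @param features the feature matrix the result was fit on.
#' @param ic50s the ln IC50 vector the result was fit on.
#' @param n_perm number of permutations (at least 19; default 100).
#' @param seed integer seed.
#' @param repeats CV repeats per permutation (default 1).
#' @return the permutation p-value, with the permuted statistics in
#'   attribute `perm_stats`. BH FDR across drugs is applied by the caller
#'   (see [lobico_scan()]).
#' @export
permutation_significance <- function(result, features, ic50s, n_perm = 100,
                                     seed = 1, repeats = 1) {
  stopifnot(inherits(result, "lobico_result"), n_perm >= 19)
  if (inherits(features, "alteration_matrix")) features <- features$values
  if (!is.null(names(ic50s))) features <- features[names(ic50s), , drop = FALSE]
  keep <- !is.na(ic50s)
  ic50s <- ic50s[keep]; features <- features[keep, , drop = FALSE]
  st <- result$settings
  lib <- logic_library(features[, st$features, drop = FALSE], st$complexities)
  observed <- min(result$cv_error)
  stats <- numeric(n_perm)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- sample(ic50s)
      eng <- lobico_engine(lib, perm, result$theta, st$complexities,
                           st$folds, repeats, seed = NULL,
                           min_specificity = st$min_specificity)
      stats[i] <- min(eng$cv_means)
    }
  })
  p <- (1 + sum(stats <= observed + 1e-12)) / (n_perm + 1)
  attr(p, "perm_stats") <- stats
  p
}

#' Logic-model scan across drugs
#'
#' Runs [lobico_cv()] and [permutation_significance()] for every drug with
#' at least `min_sensitive` sensitive cell lines, then controls the FDR
#' across drugs with [bh_fdr()]. A drug's model is `predictive` when its
#' permutation p-value is below `p_thr` and its FDR below `fdr_thr`
#' (defaults 0.05 and 5%).
#'
#' @param responses a [drug_response()].
#' @param features binary matrix or [alteration_matrix()] of CFEs.
#' @param theta per-drug binarization thresholds: `"max_conc"` (default,
#'   log of each drug's maximum tested concentration) or a named numeric
#'   vector.
#' @param n_perm permutations per drug.
#' @param seed integer seed.
#' @param ... passed to [lobico_cv()].
#' @return list with `results` (named list of `lobico_result`, each gaining
#'   `permutation_p`, `fdr` and `predictive`), `summary` (one row per
#'   attempted drug) and `skipped` (drugs without enough sensitive lines).
#' @export
lobico_scan <- function(responses, features, theta = "max_conc",
                        n_perm = 100, seed = 1, p_thr = 0.05,
                        fdr_thr = 0.05, ...) {
  stopifnot(inherits(responses, "drug_response"))
  if (inherits(features, "alteration_matrix")) features <- features$values
  drugs <- colnames(responses$ic50)
  thetas <- if (identical(theta, "max_conc"))
    log(responses$max_conc[drugs]) else theta[drugs]
  results <- list(); skipped <- character(0)
  for (i in seq_along(drugs)) {
    d <- drugs[i]
    ic <- responses$ic50[, d]
    ic <- ic[rownames(features)[rownames(features) %in% names(ic)]]
    res <- tryCatch(
      lobico_cv(features, ic, thetas[d], seed = seed + i, ...),
      error = function(e) NULL)
    if (is.null(res)) { skipped <- c(skipped, d); next }
    res$permutation_p <- as.numeric(
      permutation_significance(res, features, ic, n_perm = n_perm,
                               seed = seed + 10000L + i))
    results[[d]] <- res
  }
  fdr <- bh_fdr(vapply(results, `[[`, 0, "permutation_p"))
  for (d in names(results)) {
    results[[d]]$fdr <- fdr[[d]]
    results[[d]]$predictive <- results[[d]]$permutation_p < p_thr &&
      fdr[[d]] < fdr_thr
  }
  summary <- do.call(rbind, lapply(names(results), function(d) {
    r <- results[[d]]
    data.frame(drug_id = d, selected = r$selected,
               cv_error = unname(r$cv_error[r$selected]),
               formula = format(r$model$formula),
               precision = r$model$precision, recall = r$model$recall,
               specificity = r$model$specificity,
               permutation_p = r$permutation_p, fdr = r$fdr,
               predictive = r$predictive)
  }))
  list(results = results, summary = summary, skipped = skipped)
}

#' Feature importance across logic-model fits
#'
#' Scores each CFE by how often it appears in the winning formulas across
#' CV folds and repeats at each drug's selected complexity, normalized to
#' sum 1 over the whole dataset, then aggregated into CFE-class categories
#' (amplified/deleted RACS, CG mutation, iCpG methylation, pathway
#' activity, fusion).
#'
#' @param results a [lobico_scan()] output, or a (possibly named) list of
#'   [lobico_cv()] results.
#' @param classes optional named character vector mapping CFE id to CFE
#'   class (e.g. from a catalog's `cfes` table); enables the per-category
#'   aggregation.
#' @return list with `feature` (named numeric vector summing to 1) and
#'   `category` (named numeric vector, `NULL` without `classes`).
#' @export
feature_importance <- function(results, classes = NULL) {
  if (!is.null(results$results)) results <- results$results
  counts <- list()
  for (r in results) {
    stopifnot(inherits(r, "lobico_result"))
    picked <- r$fold_models[r$selected, ]
    for (fm in picked) for (f in fm[[1]])
      counts[[f]] <- (counts[[f]] %||% 0) + 1
  }
  if (length(counts) == 0)
    return(list(feature = numeric(0), category = NULL))
  feature <- unlist(counts)
  feature <- sort(feature / sum(feature), decreasing = TRUE)
  category <- NULL
  if (!is.null(classes)) {
    labels <- c(CG = "CG mutation", RACS_amp = "amplified RACS",
                RACS_del = "deleted RACS", iCpG = "iCpG methylation",
                fusion = "fusion", pathway_activity = "pathway activity")
    cat_of <- labels[classes[names(feature)]]
    category <- tapply(feature, cat_of, sum)
    category <- setNames(as.numeric(category), names(category))
  }
  list(feature = feature, category = category)
}
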