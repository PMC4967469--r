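#' Per-cancer-type CFE frequency profiles
#'
#' Column means of the alteration matrix over non-missing entries, split by
#' cancer type and cohort — the fingerprints compared between tumors and
#' cell lines.
#'
#' @param matrix an [alteration_matrix()].
#' @return long data frame with `cohort`, `cancer_type`, `cfe_id`,
#'   `frequency`, `n_samples`; empty groups are skipped.
#' @export
frequency_profiles <- function(matrix) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  ann <- matrix$annotations
  out <- list()
  for (co in unique(ann$cohort)) for (ct in unique(ann$cancer_type)) {
    rows <- which(ann$cohort == co & ann$cancer_type == ct)
    if (length(rows) == 0) next
    f <- colMeans(matrix$values[rows, , drop = FALSE], na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      cohort = co, cancer_type = ct, cfe_id = names(f),
      frequency = unname(f), n_samples = length(rows))
  }
  do.call(rbind, out)
}

#' Reshape frequency profiles to a cancer-type by CFE matrix
#'
#' @param profiles output of [frequency_profiles()].
#' @param cohort optional cohort filter (`"tumor"` or `"cell_line"`).
#' @return numeric matrix, one row per cancer type.
#' @export
profile_matrix <- function(profiles, cohort = NULL) {
  if (!is.null(cohort)) profiles <- profiles[profiles$cohort == cohort, ]
  types <- sort(unique(profiles$cancer_type))
  cfes <- sort(unique(profiles$cfe_id))
  m <- matrix(NA_real_, length(types), length(cfes),
              dimnames = list(types, cfes))
  m[cbind(match(profiles$cancer_type, types),
          match(profiles$cfe_id, cfes))] <- profiles$frequency
  m
}

#' Pearson correlation between frequency profiles
#'
#' @param profiles_a,profiles_b cancer-type by CFE matrices
#'   (see [profile_matrix()]) sharing a CFE universe.
#' @return correlation matrix, rows = profiles of `a`, columns = profiles of
#'   `b`; `NA` where a profile has zero variance.
#' @export
profile_correlation <- function(profiles_a, profiles_b) {
  shared <- intersect(colnames(profiles_a), colnames(profiles_b))
  stopifnot(length(shared) >= 2)
  a <- t(profiles_a[, shared, drop = FALSE])
  b <- t(profiles_b[, shared, drop = FALSE])
  suppressWarnings(cor(a, b, use = "pairwise.complete.obs"))
}

#' Nearest-neighbor tissue matching between cohorts
#'
#' For every cell line profile, ranks the tumor profiles by correlation
#' distance (1 - Pearson over the shared CFEs) and asks whether the same
#' cancer type appears within the top `k` neighbors; likewise in the
#' reverse direction, and pools both (cell lines to tumors and vice versa)
#' into one accuracy.
#'
#' @param cell_profiles,tumor_profiles cancer-type by CFE matrices (at least
#'   2 cancer types each).
#' @param k neighborhood size (default 1).
#' @return list with `accuracy` (pooled top-k accuracy) and `matches` (one
#'   row per query profile: direction, true type, nearest type, rank of the
#'   true type, correct flag). Profiles with no computable correlation are
#'   excluded.
#' @export
nn_tissue_match <- function(cell_profiles, tumor_profiles, k = 1) {
  stopifnot(nrow(cell_profiles) >= 2, nrow(tumor_profiles) >= 2)
  cc <- profile_correlation(cell_profiles, tumor_profiles)
  one_dir <- function(cm, direction) {
    out <- list()
    for (q in rownames(cm)) {
      r <- cm[q, ]
      r <- r[!is.na(r)]
      if (length(r) == 0 || !(q %in% names(r))) next
      ranks <- rank(1 - r, ties.method = "min")
      nn <- names(r)[which.min(1 - r)]
      out[[length(out) + 1L]] <- data.frame(
        direction = direction, true_type = q, nn_type = nn,
        rank_of_true = unname(ranks[q]),
        correct = unname(ranks[q]) <= k)
    }
    do.call(rbind, out)
  }
  matches <- rbind(one_dir(cc, "cell_to_tumor"),
                   one_dir(t(cc), "tumor_to_cell"))
  list(accuracy = mean(matches$correct), matches = matches)
}

#' Pathway-level alteration-frequency concordance
#'
#' Per pathway and cancer type, the fraction of samples with at least one
#' altered CFE mapped to the pathway, computed in each cohort; the
#' per-pathway Pearson correlation across cancer types measures how well
#' cell lines recapitulate tumor pathway alteration frequencies.
#'
#' @param tumors,cell_lines [alteration_matrix()] objects.
#' @param pathway_map data frame with columns `pathway`, `cfe_id`.
#' @return list with `per_pathway` (data frame: `pathway`, `r`, `n_types`)
#'   and `median_r`; a pathway with no mapped CFEs present yields `NA`.
#' @export
pathway_frequency_correlation <- function(tumors, cell_lines, pathway_map) {
  stopifnot(nrow(pathway_map) >= 1,
            all(c("pathway", "cfe_id") %in% names(pathway_map)))
  types <- intersect(unique(tumors$annotations$cancer_type),
                     unique(cell_lines$annotations$cancer_type))
  frac <- function(am, cfes, ct) {
    rows <- which(am$annotations$cancer_type == ct)
    cfes <- intersect(cfes, colnames(am$values))
    if (length(cfes) == 0 || length(rows) == 0) return(NA_real_)
    sub <- am$values[rows, cfes, drop = FALSE]
    hit <- rowSums(sub == 1, na.rm = TRUE) > 0
    all_na <- rowSums(!is.na(sub)) == 0
    mean(hit[!all_na])
  }
  out <- lapply(split(pathway_map$cfe_id, pathway_map$pathway), function(cfes) {
    ft <- vapply(types, function(ct) frac(tumors, cfes, ct), numeric(1))
    fc <- vapply(types, function(ct) frac(cell_lines, cfes, ct), numeric(1))
    ok <- !is.na(ft) & !is.na(fc)
    r <- if (sum(ok) >= 3 && sd(ft[ok]) > 0 && sd(fc[ok]) > 0)
      cor(ft[ok], fc[ok]) else NA_real_
    data.frame(r = r, n_types = sum(ok))
  })
  per <- do.call(rbind, out)
  per <- data.frame(pathway = rownames(per), per, row.names = NULL)
  list(per_pathway = per, median_r = median(per$r, na.rm = TRUE))
}

#' Assign each sample a global CFE class
#'
#' The class-level burden of a sample is its count of altered CFEs of each
#' class, normalized by the cohort-wide mean count for that class; the
#' sample's global class is the argmax burden among M (CG mutations),
#' H (iCpG hypermethylation), CD (deleted RACS) and CA (amplified RACS),
#' ties broken in that priority order. Samples with zero burden in every
#' class are unclassified.
#'
#' @param matrix an [alteration_matrix()].
#' @param catalog the governing [cfe_catalog()].
#' @return data frame with `sample_id`, `cancer_type`, `cohort`, `class`
#'   (`"M"`, `"H"`, `"CD"`, `"CA"` or `NA`) and the four normalized burden
#'   scores.
#' @export
assign_global_class <- function(matrix, catalog) {
  stopifnot(inherits(matrix, "alteration_matrix"),
            inherits(catalog, "cfe_catalog"))
  class_map <- c(CG = "M", iCpG = "H", RACS_del = "CD", RACS_amp = "CA")
  cls <- setNames(catalog$cfes$cfe_class, catalog$cfes$cfe_id)
  classes <- c("M", "H", "CD", "CA")
  counts <- sapply(classes, function(gc) {
    ids <- names(cls)[cls == names(class_map)[class_map == gc]]
    ids <- intersect(ids, colnames(matrix$values))
    if (length(ids) == 0) return(rep(0, nrow(matrix$values)))
    rowSums(matrix$values[, ids, drop = FALSE] == 1, na.rm = TRUE)
  })
  counts <- matrix(counts, nrow = nrow(matrix$values),
                   dimnames = list(rownames(matrix$values), classes))
  bg <- colMeans(counts)
  burden <- sweep(counts, 2, ifelse(bg > 0, bg, NA), "/")
  assigned <- apply(burden, 1, function(b) {
    b[is.na(b)] <- 0
    if (all(b == 0)) return(NA_character_)
    classes[which.max(b)]  # which.max takes the first: priority M > H > CD > CA
  })
  data.frame(sample_id = rownames(matrix$values),
             cancer_type = matrix$annotations$cancer_type,
             cohort = matrix$annotations$cohort,
             class = unname(assigned),
             burden_M = burden[, "M"], burden_H = burden[, "H"],
             burden_CD = burden[, "CD"], burden_CA = burden[, "CA"],
             row.names = NULL)
}

modal_class <- function(cls) {
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) return(NA_character_)
  tab <- table(factor(cls, levels = c("M", "H", "CD", "CA")))
  names(tab)[which.max(tab)]  # first max: priority order on ties
}

#' Concordance of predominant global classes between cohorts
#'
#' Per cancer type, the modal global class of the tumor cohort is compared
#' with that of the cell line cohort; concordant when they agree.
#'
#' @param tumor_assignments,cell_assignments outputs of
#'   [assign_global_class()].
#' @return data frame with `cancer_type`, `tumor_class`, `cell_class`,
#'   `concordant`, plus attribute `fraction_concordant`.
#' @export
class_concordance <- function(tumor_assignments, cell_assignments) {
  types <- intersect(unique(tumor_assignments$cancer_type),
                     unique(cell_assignments$cancer_type))
  out <- do.call(rbind, lapply(types, function(ct) {
    tc <- modal_class(tumor_assignments$class[
      tumor_assignments$cancer_type == ct])
    cc <- modal_class(cell_assignments$class[
      cell_assignments$cancer_type == ct])
    data.frame(cancer_type = ct, tumor_class = tc, cell_class = cc,
               concordant = !is.na(tc) && !is.na(cc) && tc == cc)
  }))
  attr(out, "fraction_concordant") <- mean(out$concordant)
  out
}

#' Patient stratification landscape
#'
#' For each cancer type and compound, the percentage of tumor samples
#' carrying at least one sensitizing single-CFE marker, and separately the
#' percentage satisfying at least one sensitivity logic formula — the
#' population a genomically stratified trial of that compound could
#' enroll. Rows with `drug_id = "__any__"` accumulate over all compounds.
#'
#' @param tumor_matrix an [alteration_matrix()] of tumors.
#' @param single_markers optional data frame of sensitizing associations
#'   with columns `drug_id`, `cfe_id` (e.g. the sensitizing significant
#'   rows of a [run_scan()] table).
#' @param logic_markers optional named list (names = drug ids) of
#'   [logic_formula()] / `logic_model` sensitivity rules.
#' @return data frame with `cancer_type`, `drug_id`, `marker_type`
#'   (`"single"` or `"logic"`), `percent` (of tumor samples, 0-100) and
#'   `n_markers`. Markers referencing CFEs absent from the tumor matrix are
#'   skipped and reported in attribute `skipped_markers`.
#' @export
stratification_landscape <- function(tumor_matrix, single_markers = NULL,
                                     logic_markers = NULL) {
  stopifnot(inherits(tumor_matrix, "alteration_matrix"))
  ann <- tumor_matrix$annotations
  types <- sort(unique(ann$cancer_type))
  X <- tumor_matrix$values
  skipped <- character(0)
  rows <- list()
  pct <- function(hit, ct) {
    s <- hit[ann$cancer_type == ct]
    if (length(s) == 0) NA_real_ else 100 * mean(s, na.rm = TRUE)
  }
  add <- function(ct, drug, type, hit, nm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cancer_type = ct, drug_id = drug, marker_type = type,
      percent = pct(hit, ct), n_markers = nm)
  }
  any_single <- rep(FALSE, nrow(X))
  if (!is.null(single_markers) && nrow(single_markers) > 0) {
    present <- single_markers$cfe_id %in% colnames(X)
    skipped <- c(skipped, unique(single_markers$cfe_id[!present]))
    single_markers <- single_markers[present, , drop = FALSE]
    for (d in unique(single_markers$drug_id)) {
      cfes <- unique(single_markers$cfe_id[single_markers$drug_id == d])
      hit <- rowSums(X[, cfes, drop = FALSE] == 1, na.rm = TRUE) > 0
      any_single <- any_single | hit
      for (ct in types) add(ct, d, "single", hit, length(cfes))
    }
    for (ct in types) add(ct, "__any__", "single", any_single, nrow(single_markers))
  }
  any_logic <- rep(FALSE, nrow(X))
  if (!is.null(logic_markers) && length(logic_markers) > 0) {
    for (d in names(logic_markers)) {
      f <- logic_markers[[d]]
      if (inherits(f, "logic_model")) f <- f$formula
      if (!all(formula_features(f) %in% colnames(X))) {
        skipped <- c(skipped, setdiff(formula_features(f), colnames(X)))
        next
      }
      hit <- evaluate_formula(f, X)
      hit[is.na(hit)] <- FALSE
      any_logic <- any_logic | hit
      for (ct in types) add(ct, d, "logic", hit, 1L)
    }
    for (ct in types) add(ct, "__any__", "logic", any_logic,
                          length(logic_markers))
  }
  res <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cancer_type = character(), drug_id = character(),
               marker_type = character(), percent = numeric(),
               n_markers = integer())
  attr(res, "skipped_markers") <- unique(skipped)
  res
}

#' A deterministic toy pathway map
#'
#' Assigns the catalog's CFEs round-robin to `n_pathways` named pathways —
#' a stand-in for curated pathway gene sets when exercising
#' [pathway_frequency_correlation()] on synthetic cohorts.
#'
#' @param catalog a [cfe_catalog()].
#' @param n_pathways number of pathways (default 13).
#' @return data frame with columns `pathway`, `cfe_id`.
#' @export
toy_pathway_map <- function(catalog, n_pathways = 13) {
  ids <- sort(catalog$cfes$cfe_id)
  data.frame(pathway = sprintf("pathway%02d",
                               rep_len(seq_len(n_pathways), length(ids))),
             cfe_id = ids)
}
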