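#' Methylation beta-value tables
#'
#' @param betas numeric matrix of beta values in `[0, 1]`, CpG islands in rows
#'   (rownames are island ids), samples in columns (colnames are sample ids).
#' @param cancer_types character vector of cancer-type labels, one per sample
#'   (recycled if length 1).
#' @return an object of class `methylation_table`.
#' @export
methylation_table <- function(betas, cancer_types) {
  stopifnot(is.matrix(betas), !is.null(rownames(betas)), !is.null(colnames(betas)))
  if (any(is.na(betas)) || any(betas < 0 | betas > 1))
    stop("beta values must lie in [0, 1]")
  if (length(cancer_types) == 1)
    cancer_types <- rep(cancer_types, ncol(betas))
  stopifnot(length(cancer_types) == ncol(betas))
  structure(list(betas = betas,
                 cancer_types = setNames(as.character(cancer_types),
                                         colnames(betas))),
            class = "methylation_table")
}

#' @export
print.methylation_table <- function(x, ...) {
  cat(sprintf("methylation_table: %d islands x %d samples\n",
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

#' Detect informative (multimodal) CpG islands
#'
#' Promoter CpG islands whose methylation signal is multimodal across samples
#' carry a binarizable hyper- vs non-hypermethylated state. The test fits 1-
#' and 2-component Gaussian mixtures (unequal variances) to the
#' logit-transformed beta values and calls the island informative when the
#' 2-component model is preferred by BIC, the component means are separated by
#' at least `min_separation` logit units, and both mixing weights are at least
#' `min_component_weight`. For informative islands, the discretization
#' threshold is the beta value between the two component means at which
#' posterior membership is equal; samples above it are later labeled
#' hypermethylated.
#'
#' @param betas numeric vector of at least 30 beta values in `[0, 1]`.
#' @param min_separation minimum distance between component means, on the
#'   logit scale (default 1.0).
#' @param min_component_weight minimum mixing weight of either component
#'   (default 0.05).
#' @return list with `informative` (logical), `threshold` (beta value, or
#'   `NA` when not informative), and the fitted `means`, `sds`, `weights`
#'   (logit scale) and `bic` (named vector for the 1- and 2-component fits).
#' @export
detect_informative_cpg <- function(betas, min_separation = 1,
                                   min_component_weight = 0.05) {
  if (any(is.na(betas)) || any(betas < 0 | betas > 1))
    stop("beta values must lie in [0, 1]")
  if (length(betas) < 30)
    stop("at least 30 beta values are required")
  eps <- 1e-3  # guard the logit against exact 0/1
  x <- qlogis(pmin(pmax(betas, eps), 1 - eps))
  not_informative <- list(informative = FALSE, threshold = NA_real_,
                          means = NULL, sds = NULL, weights = NULL, bic = NULL)
  if (stats::sd(x) < 1e-8) return(not_informative)
  fit <- tryCatch(
    mclust::Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(not_informative)
  bic <- setNames(c(fit$BIC["1", "V"], fit$BIC["2", "V"]), c("G1", "G2"))
  if (is.na(bic["G2"]) || (!is.na(bic["G1"]) && bic["G1"] >= bic["G2"]))
    return(modifyList(not_informative, list(bic = bic)))
  fit2 <- if (fit$G == 2) fit else
    tryCatch(mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
             error = function(e) NULL)
  if (is.null(fit2)) return(modifyList(not_informative, list(bic = bic)))
  mu <- as.numeric(fit2$parameters$mean)
  sig <- sqrt(as.numeric(fit2$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, 2)
  w <- as.numeric(fit2$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]; w <- w[ord]
  ok <- (mu[2] - mu[1]) >= min_separation && all(w >= min_component_weight)
  thr <- if (ok) equal_posterior_point(mu, sig, w) else NA_real_
  list(informative = ok, threshold = if (ok) plogis(thr) else NA_real_,
       means = mu, sds = sig, weights = w, bic = bic)
}

# logit-scale point between the two means where posterior membership is equal
equal_posterior_point <- function(mu, sig, w) {
  f <- function(x) {
    (log(w[1]) + dnorm(x, mu[1], sig[1], log = TRUE)) -
      (log(w[2]) + dnorm(x, mu[2], sig[2], log = TRUE))
  }
  if (f(mu[1]) > 0 && f(mu[2]) < 0)
    return(uniroot(f, c(mu[1], mu[2]), tol = 1e-10)$root)
  grid <- seq(mu[1], mu[2], length.out = 4001)  # fallback for skewed fits
  grid[which.min(abs(f(grid)))]
}

#' Threshold every island of a methylation table
#'
#' Applies [detect_informative_cpg()] across the rows of a
#' [methylation_table()].
#'
#' @param table a [methylation_table()].
#' @inheritParams detect_informative_cpg
#' @return named numeric vector of per-island beta thresholds (`NA` for
#'   non-informative islands).
#' @export
informative_cpg_thresholds <- function(table, min_separation = 1,
                                       min_component_weight = 0.05) {
  stopifnot(inherits(table, "methylation_table"))
  vapply(rownames(table$betas), function(i) {
    detect_informative_cpg(table$betas[i, ], min_separation,
                           min_component_weight)$threshold
  }, numeric(1))
}

#' Binarize methylation into hypermethylation calls
#'
#' A sample is called hypermethylated at an island when its beta value is
#' strictly above the island's discretization threshold. Islands without a
#' threshold (non-informative) are dropped.
#'
#' @param table a [methylation_table()].
#' @param thresholds named numeric vector of per-island beta thresholds, as
#'   from [informative_cpg_thresholds()]; `NA` entries are dropped.
#' @param cohort cohort label for the resulting annotations (default
#'   `"cell_line"`).
#' @return an [alteration_matrix()], samples by informative islands.
#' @export
binarize_methylation <- function(table, thresholds, cohort = "cell_line") {
  stopifnot(inherits(table, "methylation_table"))
  thresholds <- thresholds[!is.na(thresholds)]
  islands <- intersect(rownames(table$betas), names(thresholds))
  vals <- t(table$betas[islands, , drop = FALSE] > thresholds[islands]) * 1L
  ann <- data.frame(sample_id = colnames(table$betas), cohort = cohort,
                    cancer_type = unname(table$cancer_types), msi = "unknown")
  alteration_matrix(vals, ann)
}
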