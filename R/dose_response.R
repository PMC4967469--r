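#' Drug response tables
#'
#' Per (cell line, drug) summaries of drug sensitivity: natural-log IC50
#' (ln uM) and, when derived from curve fits, AUC. Each drug carries one
#' maximum tested concentration.
#'
#' @param ic50 numeric matrix of ln IC50 values (ln uM), cell lines in rows,
#'   drugs in columns; `NA` allowed.
#' @param max_conc named numeric vector, maximum tested concentration (uM)
#'   per drug; names must cover the columns of `ic50`.
#' @param auc optional numeric matrix of AUC values in `[0, 1]`, same shape
#'   as `ic50`.
#' @return an object of class `drug_response`.
#' @export
drug_response <- function(ic50, max_conc, auc = NULL) {
  stopifnot(is.matrix(ic50), !is.null(rownames(ic50)), !is.null(colnames(ic50)))
  if (!all(colnames(ic50) %in% names(max_conc)))
    stop("every drug must have a maximum tested concentration")
  max_conc <- max_conc[colnames(ic50)]
  if (!is.null(auc))
    stopifnot(identical(dim(auc), dim(ic50)),
              all(is.na(auc) | (auc >= 0 & auc <= 1)))
  structure(list(ic50 = ic50, auc = auc, max_conc = max_conc),
            class = "drug_response")
}

#' @export
print.drug_response <- function(x, ...) {
  cat(sprintf("drug_response: %d cell lines x %d drugs (%.0f%% measured)\n",
              nrow(x$ic50), ncol(x$ic50), 100 * mean(!is.na(x$ic50))))
  invisible(x)
}

curve_model <- function(log_conc, ln_ic50, slope) {
  1 / (1 + exp(slope * (log_conc - ln_ic50)))
}

#' Fit a two-parameter logistic dose-response curve
#'
#' Least-squares fit of `viability = 1 / (1 + exp(slope * (ln c - ln IC50)))`
#' with asymptotes fixed at 1 (no effect) and 0 (complete kill), the minimal
#' identifiable summary for 5-9 point screening curves. The optimizer starts
#' from a fixed multi-start grid (slope in {0.5, 1, 2, 4} crossed with ln IC50
#' at the tested-range quartiles) so fits are deterministic. The ln IC50 is
#' unconstrained; fits beyond the highest tested concentration are flagged as
#' extrapolated rather than capped.
#'
#' @param concentrations tested concentrations in uM, strictly decreasing
#'   (dilution order), at least 5 points.
#' @param viabilities fractions of control viability, same length.
#' @return an object of class `curve_fit`: list with `ln_ic50` (ln uM),
#'   `slope` (> 0), `auc` (mean fitted viability over the tested
#'   log-concentration range, in `[0, 1]`), `rmse` (viability units),
#'   `extrapolated` (ln IC50 above the tested range) and `converged`. A
#'   failed optimization returns `rmse = Inf` with `converged = FALSE`.
#' @examples
#' conc <- 10 / 2^(0:8)
#' v <- 1 / (1 + exp(1 * (log(conc) - 0)))
#' fit_curve(conc, v)
#' @export
fit_curve <- function(concentrations, viabilities) {
  stopifnot(length(concentrations) == length(viabilities),
            length(concentrations) >= 5)
  if (any(!is.finite(viabilities)) || any(!is.finite(concentrations)))
    stop("non-finite values in dose-response curve")
  if (any(diff(concentrations) >= 0))
    stop("concentrations must be strictly decreasing")
  lx <- log(concentrations)
  sse <- function(par) sum((viabilities - curve_model(lx, par[1], par[2]))^2)
  starts <- expand.grid(ln_ic50 = quantile(lx, c(0, 0.25, 0.5, 0.75, 1)),
                        slope = c(0.5, 1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(as.numeric(starts[i, ]), sse,
                    lower = c(-30, 1e-3), upper = c(30, 50)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(ln_ic50 = NA_real_, slope = NA_real_, auc = NA_real_,
                          rmse = Inf, extrapolated = NA, converged = FALSE),
                     class = "curve_fit"))
  }
  ln_ic50 <- best$par[1]; slope <- best$par[2]
  structure(list(
    ln_ic50 = ln_ic50, slope = slope,
    auc = compute_auc(ln_ic50, slope, range(lx)),
    rmse = sqrt(best$objective / length(viabilities)),
    extrapolated = ln_ic50 > max(lx), converged = TRUE),
    class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("curve_fit: ln IC50 = %.3f, slope = %.3f, AUC = %.3f, RMSE = %.3g%s\n",
              x$ln_ic50, x$slope, x$auc, x$rmse,
              if (isTRUE(x$extrapolated)) " (extrapolated)" else ""))
  invisible(x)
}

#' Area under the fitted dose-response curve
#'
#' Mean of the fitted viability over the tested log-concentration interval,
#' clipped to `[0, 1]`: 1 means no drug effect over the tested range, 0
#' complete kill. Uses the closed-form antiderivative of the logistic.
#'
#' @param ln_ic50,slope fitted curve parameters (or a `curve_fit` as
#'   `ln_ic50` with `slope` missing).
#' @param log_conc_range length-2 numeric, range of tested log
#'   concentrations.
#' @return AUC fraction in `[0, 1]`.
#' @export
compute_auc <- function(ln_ic50, slope, log_conc_range) {
  if (inherits(ln_ic50, "curve_fit")) {
    fit <- ln_ic50
    slope <- fit$slope
    ln_ic50 <- fit$ln_ic50
  }
  lo <- min(log_conc_range); hi <- max(log_conc_range)
  softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))
  anti <- function(x) x - softplus(slope * (x - ln_ic50)) / slope
  min(max((anti(hi) - anti(lo)) / (hi - lo), 0), 1)
}

#' Fit every curve of a long-format dose-response table
#'
#' @param curves data frame with columns `drug_id`, `sample_id`, `conc_uM`,
#'   `viability` (as produced by [simulate_dose_response()]).
#' @return a [drug_response()] with ln IC50 and AUC matrices, plus an
#'   `extrapolated` indicator matrix in the `fits` attribute.
#' @export
fit_curves <- function(curves) {
  stopifnot(all(c("drug_id", "sample_id", "conc_uM", "viability") %in%
                  names(curves)))
  drugs <- sort(unique(curves$drug_id))
  samples <- sort(unique(curves$sample_id))
  ic50 <- auc <- extr <- matrix(NA_real_, length(samples), length(drugs),
                                dimnames = list(samples, drugs))
  max_conc <- setNames(numeric(length(drugs)), drugs)
  for (d in drugs) {
    sub <- curves[curves$drug_id == d, ]
    max_conc[d] <- max(sub$conc_uM)
    for (s in unique(sub$sample_id)) {
      cur <- sub[sub$sample_id == s, ]
      ord <- order(cur$conc_uM, decreasing = TRUE)
      fit <- fit_curve(cur$conc_uM[ord], cur$viability[ord])
      ic50[s, d] <- fit$ln_ic50
      auc[s, d] <- fit$auc
      extr[s, d] <- as.numeric(fit$extrapolated)
    }
  }
  res <- drug_response(ic50, max_conc, auc = auc)
  attr(res, "extrapolated") <- extr
  res
}

#' Replicate concordance of IC50 profiles
#'
#' Agreement between two replicate screens of the same drug: Pearson
#' correlation of ln IC50 over shared cell lines, and consistency of the
#' sensitive/resistant classification (sensitive when IC50 is at or below the
#' maximum tested concentration) summarized by a one-sided Fisher exact test.
#'
#' @param ic50_a,ic50_b named numeric vectors of ln IC50 (ln uM) per cell
#'   line; at least 10 shared cell lines are required.
#' @param max_conc maximum tested concentration in uM.
#' @return list with `pearson_r`, `fet_log10_p` (log10 of the one-sided
#'   Fisher exact p for positive association) and `table` (the 2x2
#'   sensitive/resistant contingency table).
#' @export
replicate_concordance <- function(ic50_a, ic50_b, max_conc) {
  shared <- intersect(names(ic50_a), names(ic50_b))
  shared <- shared[!is.na(ic50_a[shared]) & !is.na(ic50_b[shared])]
  if (length(shared) < 10)
    stop("at least 10 shared cell lines are required")
  a <- ic50_a[shared]; b <- ic50_b[shared]
  lab <- function(x) factor(ifelse(x <= log(max_conc), "sensitive", "resistant"),
                            levels = c("sensitive", "resistant"))
  tab <- table(replicate_a = lab(a), replicate_b = lab(b))
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(pearson_r = cor(a, b), fet_log10_p = log10(p), table = tab)
}
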