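#' Simulation configuration for paired tumor/cell-line cohorts
#'
#' Describes the statistical structure the pipeline assumes in real screens:
#' per-cancer-type cohorts whose binary cancer functional events (CFEs) are
#' independent Bernoulli draws at tumor-derived frequencies shared exactly
#' between tumors and cell lines, and natural-log IC50 drug responses built
#' from a per-drug baseline plus planted additive and logic (AND/OR) effects
#' plus Gaussian noise.
#'
#' @param cancer_types character vector of cancer-type labels.
#' @param n_tumors,n_cell_lines integer counts per cancer type (recycled).
#' @param cfes data frame with columns `cfe_id` and `cfe_class`.
#' @param frequencies data frame with columns `cfe_id`, `cancer_type` and
#'   `frequency` in `[0, 1]`; the same frequencies generate both cohorts.
#' @param drugs data frame with columns `drug_id`, `baseline` (mean ln IC50,
#'   ln uM) and `max_conc` (maximum tested concentration, uM).
#' @param additive_effects data frame with columns `drug_id`, `cfe_id`,
#'   `beta` (shift in ln IC50 units for carriers; negative = sensitizing), or
#'   `NULL`.
#' @param logic_effects list of `list(drug_id =, formula =, beta =)` entries
#'   where `formula` is a [logic_formula()] over CFE ids, or `NULL`.
#' @param noise_sd Gaussian noise standard deviation on ln IC50 (default 0.5
#'   ln units).
#' @param msi_rate probability a sample is microsatellite unstable.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(cancer_types, n_tumors, n_cell_lines, cfes, frequencies,
                       drugs, additive_effects = NULL, logic_effects = NULL,
                       noise_sd = 0.5, msi_rate = 0.05, seed = 1) {
  stopifnot(length(cancer_types) >= 1, noise_sd > 0,
            all(n_tumors >= 1), all(n_cell_lines >= 1))
  n_tumors <- rep_len(as.integer(n_tumors), length(cancer_types))
  n_cell_lines <- rep_len(as.integer(n_cell_lines), length(cancer_types))
  stopifnot(all(frequencies$frequency >= 0 & frequencies$frequency <= 1),
            all(frequencies$cancer_type %in% cancer_types),
            all(frequencies$cfe_id %in% cfes$cfe_id),
            all(c("drug_id", "baseline", "max_conc") %in% names(drugs)))
  if (!is.null(additive_effects)) {
    stopifnot(all(additive_effects$cfe_id %in% cfes$cfe_id),
              all(additive_effects$drug_id %in% drugs$drug_id))
  }
  if (!is.null(logic_effects)) {
    for (ef in logic_effects) {
      stopifnot(inherits(ef$formula, "logic_formula"),
                ef$drug_id %in% drugs$drug_id)
      if (!all(formula_features(ef$formula) %in% cfes$cfe_id))
        stop("logic effect references unknown CFE")
    }
  }
  structure(list(cancer_types = cancer_types, n_tumors = n_tumors,
                 n_cell_lines = n_cell_lines, cfes = as.data.frame(cfes),
                 frequencies = as.data.frame(frequencies),
                 drugs = as.data.frame(drugs),
                 additive_effects = additive_effects,
                 logic_effects = logic_effects, noise_sd = noise_sd,
                 msi_rate = msi_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation configuration
#'
#' The canonical study conditions used throughout the package's tests and
#' vignette: six cancer types with 120 tumors and 50 cell lines each (300
#' cell lines, the scale at which planted effects of twice the noise standard
#' deviation are recoverable), 40 CFEs across the four main classes with
#' deterministic per-type frequency profiles (background frequencies cycling
#' through 0.05/0.10/0.20/0.15 and one enriched type per CFE at 0.45, giving
#' each cancer type a distinct profile), eight drugs with baseline ln IC50 of
#' 3.5 ln uM against a maximum tested concentration of 10 uM (so unaltered
#' lines are typically resistant), planted additive effects of -2 and -1.5 ln
#' units, one planted OR rule, and ln-IC50 noise of 0.5 ln units.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
default_sim_config <- function(seed = 1) {
  types <- c("BRCA", "COADREAD", "LUAD", "SKCM", "OV", "GBM")
  cfes <- data.frame(
    cfe_id = c(sprintf("CG%02d_mut", 1:16), sprintf("RACS%02d_amp", 1:8),
               sprintf("RACS%02d_del", 1:8), sprintf("iCpG%02d_meth", 1:8)),
    cfe_class = rep(c("CG", "RACS_amp", "RACS_del", "iCpG"), c(16, 8, 8, 8)))
  n_cfe <- nrow(cfes)
  base <- rep_len(c(0.05, 0.10, 0.20, 0.15), n_cfe)
  freq <- expand.grid(cfe_id = cfes$cfe_id, cancer_type = types,
                      stringsAsFactors = FALSE)
  i <- match(freq$cfe_id, cfes$cfe_id)
  freq$frequency <- base[i]
  enriched <- types[(i - 1L) %% length(types) + 1L]
  freq$frequency[enriched == freq$cancer_type] <- 0.45
  drugs <- data.frame(drug_id = sprintf("drug%02d", 1:8),
                      baseline = 3.5, max_conc = 10)
  additive <- data.frame(
    drug_id = c("drug01", "drug02"),
    cfe_id = c("CG01_mut", "RACS01_amp"),
    beta = c(-2, -1.5))
  logic <- list(list(drug_id = "drug03",
                     formula = logic_formula(list("CG02_mut", "CG03_mut"),
                                             form = "DNF"),
                     beta = -2))
  sim_config(types, n_tumors = 120, n_cell_lines = 50, cfes = cfes,
             frequencies = freq, drugs = drugs, additive_effects = additive,
             logic_effects = logic, noise_sd = 0.5, seed = seed)
}

#' Matched-cohort concordance benchmark configuration
#'
#' Study conditions for the tumor/cell-line concordance recovery analyses:
#' six cancer types (100 tumors and 40 cell lines each) whose frequency
#' profiles are made distinct by giving every type one dominant CFE class
#' (cycling CG, iCpG, deleted RACS, amplified RACS) at frequency 0.45
#' against a 0.05 background. Each type therefore has both a recoverable
#' nearest-neighbor fingerprint and a well-defined predominant global
#' class, the two signals the landscape analyses are asked to recover.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
concordance_sim_config <- function(seed = 1) {
  base <- default_sim_config(seed)
  types <- base$cancer_types
  dominant <- rep_len(c("CG", "iCpG", "RACS_del", "RACS_amp"), length(types))
  cls <- setNames(base$cfes$cfe_class, base$cfes$cfe_id)
  # types sharing a dominant class enrich disjoint halves of its CFEs, so
  # every type keeps a distinguishable fingerprint
  freq <- expand.grid(cfe_id = base$cfes$cfe_id, cancer_type = types,
                      stringsAsFactors = FALSE)
  freq$frequency <- 0.05
  for (ti in seq_along(types)) {
    members <- names(cls)[cls == dominant[ti]]
    sharing <- which(dominant == dominant[ti])
    part <- split(members, rep_len(seq_along(sharing), length(members)))
    enriched <- part[[match(ti, sharing)]]
    freq$frequency[freq$cancer_type == types[ti] &
                     freq$cfe_id %in% enriched] <- 0.45
  }
  sim_config(types, n_tumors = 100, n_cell_lines = 40, cfes = base$cfes,
             frequencies = freq, drugs = base$drugs, noise_sd = base$noise_sd,
             seed = seed)
}

#' Simulate paired tumor and cell line cohorts
#'
#' Per cancer type, each CFE is drawn as an independent Bernoulli at its
#' configured frequency, identically for tumors and cell lines (the
#' recoverable signal of the concordance analyses). Deterministic given the
#' config seed; the caller's RNG state is untouched.
#'
#' @param config a [sim_config()].
#' @return list with `tumors` and `cell_lines` ([alteration_matrix()]),
#'   `catalog` (the generating [cfe_catalog()], mode pan-cancer) and `truth`
#'   (planted frequencies and seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    draw <- function(counts, cohort, prefix) {
      n_tot <- sum(counts)
      ids <- sprintf("%s%04d", prefix, seq_len(n_tot))
      type <- rep(config$cancer_types, counts)
      vals <- matrix(0L, n_tot, nrow(config$cfes),
                     dimnames = list(ids, config$cfes$cfe_id))
      for (ct in config$cancer_types) {
        rows <- which(type == ct)
        f <- config$frequencies[config$frequencies$cancer_type == ct, ]
        p <- setNames(f$frequency, f$cfe_id)[config$cfes$cfe_id]
        p[is.na(p)] <- 0
        vals[rows, ] <- rbinom(length(rows) * length(p), 1L,
                               rep(p, each = length(rows)))
      }
      ann <- data.frame(sample_id = ids, cohort = cohort, cancer_type = type,
                        msi = ifelse(runif(n_tot) < config$msi_rate,
                                     "MSI", "MSS"))
      alteration_matrix(vals, ann)
    }
    tumors <- draw(config$n_tumors, "tumor", "T")
    cell_lines <- draw(config$n_cell_lines, "cell_line", "CL")
    catalog <- cfe_catalog(config$cfes, config$frequencies,
                           mode = "pan_cancer")
    list(tumors = tumors, cell_lines = cell_lines, catalog = catalog,
         truth = list(frequencies = config$frequencies, seed = config$seed))
  })
}

#' Simulate ln-IC50 drug responses with planted effects
#'
#' For each (drug, cell line): `ln IC50 = baseline + sum of additive
#' beta * CFE indicator + sum of logic beta * formula satisfaction +
#' N(0, noise_sd)`. Logic formulas are evaluated on the binary CFE row via
#' [evaluate_formula()].
#'
#' @param cell_lines an [alteration_matrix()].
#' @param config a [sim_config()]; a formula referencing a CFE absent from
#'   `cell_lines` is a configuration error.
#' @return list with `responses` (a [drug_response()] holding the ln-IC50
#'   matrix and per-drug maximum tested concentrations) and `truth` (the
#'   planted effects and the per-sample latent means).
#' @export
simulate_drug_response <- function(cell_lines, config) {
  stopifnot(inherits(cell_lines, "alteration_matrix"),
            inherits(config, "sim_config"))
  X <- cell_lines$values
  drugs <- config$drugs
  mu <- matrix(rep(drugs$baseline, each = nrow(X)), nrow(X), nrow(drugs),
               dimnames = list(rownames(X), drugs$drug_id))
  ae <- config$additive_effects
  if (!is.null(ae)) {
    for (k in seq_len(nrow(ae))) {
      if (!ae$cfe_id[k] %in% colnames(X))
        stop("additive effect references unknown CFE: ", ae$cfe_id[k])
      mu[, ae$drug_id[k]] <- mu[, ae$drug_id[k]] + ae$beta[k] * X[, ae$cfe_id[k]]
    }
  }
  for (ef in config$logic_effects %||% list()) {
    if (!all(formula_features(ef$formula) %in% colnames(X)))
      stop("logic effect references unknown CFE")
    sat <- evaluate_formula(ef$formula, X)
    mu[, ef$drug_id] <- mu[, ef$drug_id] + ef$beta * as.numeric(sat)
  }
  with_seed(config$seed + 1L, {
    ic50 <- mu + matrix(rnorm(length(mu), sd = config$noise_sd), nrow(mu))
    responses <- drug_response(ic50, setNames(drugs$max_conc, drugs$drug_id))
    list(responses = responses,
         truth = list(latent_means = mu, additive_effects = ae,
                      logic_effects = config$logic_effects,
                      noise_sd = config$noise_sd))
  })
}

#' Simulate raw dose-response curves from an IC50 table
#'
#' Per (drug, cell line), viabilities follow a two-parameter logistic with the
#' table's ln IC50 and a lognormal-drawn slope, evaluated at a dilution series
#' `max_conc / dilution^k`, plus Gaussian viability noise clipped to
#' `[-0.1, 1.2]` (plate-reader-like artifacts without pathological fits).
#'
#' @param responses a [drug_response()].
#' @param n_points number of concentrations per curve (at least 5).
#' @param dilution dilution factor between consecutive concentrations (> 1).
#' @param viability_noise_sd Gaussian noise on the viability scale.
#' @param seed integer seed.
#' @return list with `curves` (long data frame: `drug_id`, `sample_id`,
#'   `conc_uM`, `viability`) and `truth` (planted ln IC50s and slopes).
#' @export
simulate_dose_response <- function(responses, n_points = 9, dilution = 2,
                                   viability_noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(responses, "drug_response"), n_points >= 5, dilution > 1)
  with_seed(seed, {
    out <- list(); slopes <- list()
    for (d in colnames(responses$ic50)) {
      conc <- responses$max_conc[[d]] / dilution^(0:(n_points - 1))
      ic <- setNames(responses$ic50[, d], rownames(responses$ic50))
      ic <- ic[!is.na(ic)]
      sl <- rlnorm(length(ic), meanlog = 0, sdlog = 0.2)
      v <- outer(seq_along(ic), seq_along(conc), function(i, j) {
        1 / (1 + exp(sl[i] * (log(conc[j]) - ic[i])))
      })
      v <- v + rnorm(length(v), sd = viability_noise_sd)
      v <- pmin(pmax(v, -0.1), 1.2)
      out[[d]] <- data.frame(
        drug_id = d, sample_id = rep(names(ic), times = length(conc)),
        conc_uM = rep(conc, each = length(ic)), viability = as.vector(v))
      slopes[[d]] <- setNames(sl, names(ic))
    }
    list(curves = do.call(rbind, c(out, list(make.row.names = FALSE))),
         truth = list(ln_ic50 = responses$ic50, slopes = slopes))
  })
}

#' Simulate per-island methylation beta values
#'
#' Informative islands are drawn from a two-component logit-normal mixture
#' (low methylation around beta 0.1, high around beta 0.8, logit-scale sd
#' 0.5, per-island high-component weight uniform in `[0.3, 0.7]`); the others
#' are unimodal around beta 0.15. The ground truth records each island's
#' informativeness flag and the analytic equal-posterior threshold.
#'
#' @param n_samples,n_islands dimensions of the table.
#' @param informative_fraction fraction of islands planted as informative, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param cancer_types cancer-type labels for the samples (recycled).
#' @return list with `table` (a [methylation_table()]) and `truth`
#'   (`informative` flags and analytic `threshold` per island).
#' @export
simulate_methylation <- function(n_samples, n_islands, informative_fraction,
                                 seed = 1, cancer_types = "PANCAN") {
  stopifnot(informative_fraction >= 0, informative_fraction <= 1)
  mu <- qlogis(c(0.1, 0.8)); sd_l <- 0.5
  with_seed(seed, {
    n_inf <- round(n_islands * informative_fraction)
    informative <- rep(c(TRUE, FALSE), c(n_inf, n_islands - n_inf))
    betas <- matrix(NA_real_, n_islands, n_samples,
                    dimnames = list(sprintf("island%04d", seq_len(n_islands)),
                                    sprintf("s%04d", seq_len(n_samples))))
    thr <- rep(NA_real_, n_islands)
    for (i in seq_len(n_islands)) {
      if (informative[i]) {
        w_hi <- runif(1, 0.3, 0.7)
        hi <- runif(n_samples) < w_hi
        x <- rnorm(n_samples, mean = ifelse(hi, mu[2], mu[1]), sd = sd_l)
        thr[i] <- plogis(equal_posterior_point(mu, c(sd_l, sd_l),
                                               c(1 - w_hi, w_hi)))
      } else {
        x <- rnorm(n_samples, mean = qlogis(0.15), sd = sd_l)
      }
      betas[i, ] <- plogis(x)
    }
    list(table = methylation_table(betas, rep_len(cancer_types, n_samples)),
         truth = list(informative = setNames(informative, rownames(betas)),
                      threshold = setNames(thr, rownames(betas))))
  })
}
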