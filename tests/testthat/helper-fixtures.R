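# small in-code fixtures shared across tests

tiny_annotations <- function(ids, cohort = "cell_line", cancer_type = "LUAD",
                             msi = "MSS") {
  data.frame(sample_id = ids, cohort = cohort, cancer_type = cancer_type,
             msi = msi)
}

tiny_am <- function(values, ...) {
  alteration_matrix(values, tiny_annotations(rownames(values), ...))
}

random_am <- function(n = 6, p = 4, seed = 1, cancer_type = "LUAD",
                      na_frac = 0) {
  set.seed(seed)
  v <- matrix(rbinom(n * p, 1, 0.4), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  if (na_frac > 0) v[sample(length(v), round(na_frac * length(v)))] <- NA
  tiny_am(v, cancer_type = cancer_type)
}

tiny_catalog <- function(ids = c("f01", "f02", "f03"),
                         classes = rep("CG", length(ids)),
                         types = "LUAD", freqs = 0.3,
                         mode = "cancer_specific") {
  cfe_catalog(data.frame(cfe_id = ids, cfe_class = classes),
              expand.grid(cfe_id = ids, cancer_type = types,
                          stringsAsFactors = FALSE) |>
                transform(frequency = freqs),
              mode = mode)
}

# a null screen: independent Gaussian responses, independent Bernoulli CFEs
null_screen <- function(n_lines = 200, n_cfes = 40, n_drugs = 50, seed = 1,
                        n_types = 4, freq = 0.2, noise_sd = 0.5) {
  types <- LETTERS[seq_len(n_types)]
  cfes <- data.frame(cfe_id = sprintf("f%03d", seq_len(n_cfes)),
                     cfe_class = "CG")
  freqs <- expand.grid(cfe_id = cfes$cfe_id, cancer_type = types,
                       stringsAsFactors = FALSE)
  freqs$frequency <- freq
  cfg <- sim_config(types, n_tumors = 1,
                    n_cell_lines = ceiling(n_lines / n_types),
                    cfes = cfes, frequencies = freqs,
                    drugs = data.frame(drug_id = sprintf("d%03d", seq_len(n_drugs)),
                                       baseline = 3, max_conc = 10),
                    noise_sd = noise_sd, seed = seed)
  co <- simulate_cohort(cfg)
  dr <- simulate_drug_response(co$cell_lines, cfg)
  list(config = cfg, cohort = co, responses = dr$responses)
}

# one planted additive effect: beta = -2 * noise_sd, n_carrier of n lines
planted_screen <- function(n_lines = 300, n_carriers = 30, n_cfes = 20,
                           noise_sd = 0.5, seed = 1) {
  cfes <- data.frame(cfe_id = sprintf("f%03d", seq_len(n_cfes)),
                     cfe_class = "CG")
  freqs <- data.frame(cfe_id = cfes$cfe_id, cancer_type = "PAN",
                      frequency = 0.2)
  freqs$frequency[1] <- n_carriers / n_lines
  cfg <- sim_config("PAN", n_tumors = 1, n_cell_lines = n_lines,
                    cfes = cfes, frequencies = freqs,
                    drugs = data.frame(drug_id = "d001", baseline = 3,
                                       max_conc = 10),
                    additive_effects = data.frame(drug_id = "d001",
                                                  cfe_id = "f001",
                                                  beta = -2 * noise_sd),
                    noise_sd = noise_sd, seed = seed)
  co <- simulate_cohort(cfg)
  dr <- simulate_drug_response(co$cell_lines, cfg)
  list(config = cfg, cohort = co, responses = dr$responses)
}

# planted (A OR B) logic rule over n_cfes independent features
logic_screen <- function(n_lines = 300, n_cfes = 10, noise_sd = 0.5,
                         beta = -2, seed = 1) {
  cfes <- data.frame(cfe_id = sprintf("f%03d", seq_len(n_cfes)),
                     cfe_class = "CG")
  freqs <- data.frame(cfe_id = cfes$cfe_id, cancer_type = "PAN",
                      frequency = 0.15)
  cfg <- sim_config("PAN", n_tumors = 1, n_cell_lines = n_lines,
                    cfes = cfes, frequencies = freqs,
                    drugs = data.frame(drug_id = "d001", baseline = 3.5,
                                       max_conc = 10),
                    logic_effects = list(list(
                      drug_id = "d001",
                      formula = logic_formula(list("f001", "f002")),
                      beta = beta)),
                    noise_sd = noise_sd, seed = seed)
  co <- simulate_cohort(cfg)
  dr <- simulate_drug_response(co$cell_lines, cfg)
  list(config = cfg, cohort = co, responses = dr$responses)
}
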