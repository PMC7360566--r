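# small generator configurations used across tests

# one pair, one context; optionally noise-free
small_config <- function(seed = 1, delta = 0, noise_sd = 0.05,
                         drugs = c("PD", "PI"), format = "2D",
                         n_tech = 4, n_bio = 2) {
  cfg <- generator_config(
    cell_lines = "HCT-116", formats = format, drugs = drugs,
    n_tech = n_tech, n_bio = n_bio,
    noise_sd = setNames(noise_sd, format),
    include_single_screen = FALSE, include_death_readouts = FALSE,
    readouts = "viability", seed = seed)
  if (delta != 0) cfg <- set_interaction(cfg, drugs[1], drugs[2], delta)
  cfg
}

# simulate one pair and return its replicate-averaged mean Bliss excess
estimate_mean_excess <- function(seed, delta, noise_sd = 0.05,
                                 drugs = c("5-FU", "PAL")) {
  cfg <- small_config(seed = seed, delta = delta, noise_sd = noise_sd,
                      drugs = drugs)
  norm <- normalize_dataset(simulate_screen(cfg))
  grids <- lapply(1:2, function(b) {
    score_matrix(assemble_dose_matrices(norm, "viability", b)[[1]])
  })
  summarize_synergy(average_replicates(grids))$mean_excess
}

# 4PL evaluator used as an independent oracle (written from the curve
# definition, not via the package's predict method)
hill_curve <- function(d, upper, lower, ec50, hill) {
  lower + (upper - lower) / (1 + (d / ec50)^hill)
}

# hand-built fit object for analytic IC/AUC checks
make_fit <- function(lower, upper, ec50, hill) {
  structure(list(lower = lower, upper = upper, log10_ec50 = log10(ec50),
                 hill = hill, rss = 0, converged = TRUE),
            class = "dose_response_fit")
}

# hand-built dose matrix
make_matrix <- function(response, doses_a = c(0, 1, 2, 4, 8),
                        doses_b = c(0, 1, 2, 4, 8), bio_rep = 1L) {
  dose_matrix(cell_line = "CL", culture_format = "2D",
              drug_a = "A", drug_b = "B",
              doses_a = doses_a, doses_b = doses_b,
              response = response,
              n_tech = matrix(4L, nrow(response), ncol(response)),
              readout = "viability", bio_rep = bio_rep)
}
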