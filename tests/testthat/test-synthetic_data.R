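test_that("the generator is deterministic given the seed", {
  cfg <- small_config(seed = 101, delta = -0.1)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$records, b$records)
  c <- simulate_screen(small_config(seed = 102, delta = -0.1))
  expect_false(identical(a$records$value, c$records$value))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(generator_config(drugs = c("PD", "PD")), "drugs")
  expect_error(generator_config(noise_sd = c("2D" = -0.1, "3D" = 0.1)),
               "noise_sd")
  expect_error(generator_config(n_tech = 0), "n_tech")
  expect_error(generator_config(vehicle_signal = 0), "vehicle_signal")
  expect_error(generator_config(single_doses = c(0, 1, 2, 4)), "single_doses")
})

test_that("a null noise-free screen scores Bliss excess zero everywhere", {
  cfg <- generator_config(cell_lines = c("HCT-116", "SW-620"), formats = "2D",
                          drugs = c("5-FU", "OXA", "PAL"),
                          noise_sd = c("2D" = 0),
                          include_single_screen = FALSE,
                          include_death_readouts = FALSE,
                          readouts = "viability", seed = 1)
  norm <- normalize_dataset(simulate_screen(cfg))
  for (m in assemble_dose_matrices(norm, "viability", 1)) {
    expect_lt(max(abs(score_matrix(m)$excess)), 1e-12)
  }
})

test_that("a single seeded interaction is recovered exactly at zero noise", {
  cfg <- generator_config(cell_lines = "HCT-116", formats = "2D",
                          drugs = c("5-FU", "OXA", "PAL"),
                          noise_sd = c("2D" = 0),
                          include_single_screen = FALSE,
                          include_death_readouts = FALSE,
                          readouts = "viability", seed = 2)
  cfg <- set_interaction(cfg, "5-FU", "PAL", -0.2)
  norm <- normalize_dataset(simulate_screen(cfg))
  summaries <- dplyr::bind_rows(lapply(
    assemble_dose_matrices(norm, "viability", 1),
    function(m) summarize_synergy(score_matrix(m))))
  target <- summaries$combination == "5-FU + PAL"
  expect_equal(summaries$mean_excess[target], -0.2, tolerance = 1e-12)
  expect_equal(summaries$mean_excess[!target], rep(0, 2), tolerance = 1e-12)
})

test_that("truth_table gives closed-form expectations without sampling", {
  cfg <- small_config(seed = 3, drugs = c("OXA", "PD"))
  tt0 <- truth_table(cfg)
  expect_false(any(tt0$synergistic_true))
  expect_equal(tt0$delta, 0)

  cfg2 <- set_interaction(cfg, "OXA", "PD", -0.1)
  tt <- truth_table(cfg2)
  expect_true(tt$synergistic_true)
  # independent enumeration from the Hill curves
  hp <- cfg2$hill_params
  dose_of <- setNames(cfg2$combo_doses$doses, cfg2$combo_doses$drug)
  pa <- hp[hp$drug == "OXA", ]
  pb <- hp[hp$drug == "PD", ]
  va <- hill_curve(dose_of[["OXA"]], pa$upper, pa$lower, pa$ec50, pa$hill)
  vb <- hill_curve(dose_of[["PD"]], pb$upper, pb$lower, pb$ec50, pb$hill)
  v_obs <- pmax(outer(va, vb) - 0.1, 0)
  n_eff <- sum(v_obs - outer(va, vb) < 0 & v_obs <= 0.5)
  expect_equal(tt$n_effective_true, n_eff)
  expect_equal(tt$mean_viability_true, mean(v_obs), tolerance = 1e-12)

  # expected viability grid is nonincreasing along each dose axis
  expect_true(all(diff(va) < 0) && all(diff(vb) < 0))
})

test_that("the truth table matches the pipeline on a noise-free screen", {
  cfg <- generator_config(cell_lines = c("HCT-116", "HT-29"),
                          formats = c("2D", "3D"),
                          drugs = c("5-FU", "PAL", "PI"),
                          noise_sd = c("2D" = 0, "3D" = 0),
                          include_single_screen = FALSE,
                          include_death_readouts = FALSE,
                          readouts = "viability", seed = 4)
  cfg <- set_interaction(cfg, "PI", "PAL", -0.12, formats = "2D")
  norm <- normalize_dataset(simulate_screen(cfg))
  summaries <- dplyr::bind_rows(lapply(
    c(assemble_dose_matrices(norm, "viability", 1),
      assemble_dose_matrices(norm, "viability", 2)),
    function(m) summarize_synergy(score_matrix(m))))
  tt <- truth_table(cfg)
  joined <- dplyr::inner_join(
    summaries, tt, by = c("cell_line", "culture_format", "combination"))
  expect_equal(joined$mean_excess, joined$mean_excess_true, tolerance = 1e-12)
  expect_equal(joined$synergistic, joined$synergistic_true)
  expect_equal(joined$n_effective, joined$n_effective_true)
})

test_that("viability correlates more with confluency than with death signals", {
  cfg <- generator_config(cell_lines = "HCT-116", formats = "2D",
                          drugs = c("5Z", "OXA", "PD"),
                          seed = 5)
  norm <- normalize_dataset(simulate_screen(cfg))
  single <- norm[norm$role == "treatment" & norm$drug_b == "", ]
  means <- single |>
    dplyr::group_by(readout, drug_a, dose_a) |>
    dplyr::summarise(v = mean(value_norm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = readout, values_from = v)
  r_conf <- pearson_r(means$viability, means$confluency)$r
  r_tox <- pearson_r(means$viability, means$celltox)$r
  r_nuc <- pearson_r(means$viability, means$nucview)$r
  expect_gt(r_conf, abs(r_tox))
  expect_gt(r_conf, abs(r_nuc))
  expect_gt(r_conf, 0.9)
})
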