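test_that("Bliss expectation and excess follow the independence model", {
  expect_equal(bliss_expected_effect(0, 0), 0)
  expect_equal(bliss_expected_effect(1, 0.3), 1)
  expect_equal(bliss_expected_effect(0.5, 0.5), 0.75)
  expect_equal(bliss_expected_effect(0.3, 0.5), bliss_expected_effect(0.5, 0.3))
  expect_warning(bliss_expected_effect(1.8, 0.2), "clamped")

  expect_equal(bliss_excess(0.3, 0.6, 0.5), 0)
  expect_equal(bliss_excess(0.2, 0.6, 0.5), -0.10)
  # supra-vehicle single agents are clamped before the product
  expect_equal(bliss_excess(1, 1.3, 1.2), 0)
})

test_that("effect-scale and viability-scale Bliss formulations agree", {
  # (E_A + E_B - E_A E_B) - E_obs equals V_obs - V_A V_B with E = 1 - V
  set.seed(33)
  v_obs <- runif(1e4, 0, 1.2)
  v_a <- runif(1e4, 0, 1)
  v_b <- runif(1e4, 0, 1)
  expected_effect <- bliss_expected_effect(1 - v_a, 1 - v_b)
  expect_equal(bliss_excess(v_obs, v_a, v_b),
               expected_effect - (1 - v_obs), tolerance = 1e-12)
})

test_that("matrices equal to the outer product of their edges score zero", {
  set.seed(44)
  for (i in 1:100) {
    va <- c(1, sort(runif(4, 0.1, 1), decreasing = TRUE))
    vb <- c(1, sort(runif(4, 0.1, 1), decreasing = TRUE))
    m <- make_matrix(outer(va, vb))
    g <- score_matrix(m)
    expect_lt(max(abs(g$excess)), 1e-12)
  }
})

test_that("injected uniform deviations are recovered exactly without noise", {
  cfg <- small_config(seed = 9, delta = -0.1, noise_sd = 0,
                      drugs = c("5-FU", "PAL"))
  norm <- normalize_dataset(simulate_screen(cfg))
  g <- score_matrix(assemble_dose_matrices(norm, "viability", 1)[[1]])
  expect_equal(as.vector(g$excess), rep(-0.1, 16), tolerance = 1e-12)
})

test_that("transposing a matrix transposes the grid and keeps summaries", {
  set.seed(55)
  resp <- outer(c(1, 0.9, 0.7, 0.5, 0.4), c(1, 0.8, 0.6, 0.45, 0.3)) +
    rbind(0, cbind(0, matrix(rnorm(16, 0, 0.05), 4, 4)))
  m <- make_matrix(resp)
  mt <- dose_matrix("CL", "2D", "B", "A", m$doses_b, m$doses_a, t(resp),
                    t(m$n_tech), "viability", 1L)
  g <- score_matrix(m)
  gt <- score_matrix(mt)
  expect_equal(gt$excess, t(g$excess))
  s <- summarize_synergy(g)
  st <- summarize_synergy(gt)
  expect_equal(st$mean_excess, s$mean_excess)
  expect_equal(st$mean_viability, s$mean_viability)
  expect_equal(st$n_effective, s$n_effective)
})

test_that("replicate averaging is cellwise with missing cells skipped", {
  m1 <- make_matrix(outer(c(1, .9, .8, .7, .6), c(1, .9, .8, .7, .6)) -
                      rbind(0, cbind(0, matrix(0.2, 4, 4))))
  m2 <- make_matrix(outer(c(1, .9, .8, .7, .6), c(1, .9, .8, .7, .6)),
                    bio_rep = 2L)
  g1 <- score_matrix(m1)
  g2 <- score_matrix(m2)
  avg <- average_replicates(list(g1, g2))
  expect_equal(as.vector(avg$excess), rep(-0.1, 16))
  expect_equal(as.vector(avg$sd_excess),
               rep(stats::sd(c(-0.2, 0)), 16))
  expect_true(all(avg$n_rep == 2))

  # identical grids: same grid back, sd 0
  avg2 <- average_replicates(list(g2, g2))
  expect_equal(avg2$excess, g2$excess)
  expect_equal(max(avg2$sd_excess), 0)

  # a missing cell in one replicate leaves the other's value
  r3 <- m1$response
  r3[3, 3] <- NA
  g3 <- score_matrix(make_matrix(r3))
  avg3 <- average_replicates(list(g3, g2))
  expect_equal(avg3$excess[2, 2], 0) # only replicate 2 contributes
  expect_equal(avg3$n_rep[2, 2], 1)

  bad <- score_matrix(make_matrix(m2$response, doses_a = c(0, 1, 3, 5, 7)))
  expect_error(average_replicates(list(g1, bad)), "incompatible")
})

test_that("synergy and effectiveness gates use strict and inclusive bounds", {
  edges_a <- c(1, 0.9, 0.8, 0.7, 0.6)
  edges_b <- c(1, 0.9, 0.8, 0.7, 0.6)
  null_m <- make_matrix(outer(edges_a, edges_b))
  s0 <- summarize_synergy(score_matrix(null_m))
  expect_false(s0$synergistic) # excess exactly 0 is not synergy
  expect_equal(s0$n_effective, 0)

  # uniform viability 0.4 below every expected product: all 16 doses effective
  hi_a <- c(1, 0.95, 0.9, 0.85, 0.8)
  resp <- outer(hi_a, hi_a)
  resp[2:5, 2:5] <- 0.4 # expected products are all >= 0.64
  s <- summarize_synergy(score_matrix(make_matrix(resp)))
  expect_true(s$synergistic)
  expect_equal(s$n_effective, 16)

  # same synergy but viability above the gate: zero effective doses
  resp2 <- outer(hi_a, hi_a)
  resp2[2:5, 2:5] <- 0.6 # synergistic everywhere, all above 0.5
  s2 <- summarize_synergy(score_matrix(make_matrix(resp2)))
  expect_true(s2$synergistic)
  expect_equal(s2$n_effective, 0)

  # boundary: viability exactly 0.5 counts (inclusive); viability just above
  # does not; excess exactly 0 does not even when viability is low
  resp3 <- outer(edges_a, edges_b) # interior cells have excess exactly 0
  resp3[2, 2] <- 0.5    # excess -0.31, viability == 0.5 -> effective
  resp3[2, 3] <- 0.5001 # excess -0.22, viability just above the gate
  # cell [5, 5] keeps excess == 0 with viability 0.36 <= 0.5: strict excess gate
  s3 <- summarize_synergy(score_matrix(make_matrix(resp3)))
  expect_equal(s3$n_effective, 1)
  expect_equal(s3$effective_doses[[1]]$viability, 0.5)
})

test_that("count_synergies uses at-least-one-cell-line semantics per format", {
  base <- tidyr::expand_grid(
    culture_format = c("2D", "3D"),
    combination = c("A + B", "A + C", "B + C"),
    cell_line = c("CL1", "CL2", "CL3")
  )
  s <- dplyr::mutate(base, mean_excess = 0.05, synergistic = FALSE)
  res <- count_synergies(s)
  expect_equal(res$counts$n_synergistic, c(0, 0))

  # one combination synergistic in 2 of 3 cell lines counts once
  s2 <- s
  hit <- s2$combination == "A + B" & s2$cell_line != "CL3" &
    s2$culture_format == "2D"
  s2$mean_excess[hit] <- -0.1
  s2$synergistic[hit] <- TRUE
  res2 <- count_synergies(s2)
  expect_equal(res2$counts$n_synergistic[res2$counts$culture_format == "2D"], 1)
  expect_equal(res2$counts$n_synergistic[res2$counts$culture_format == "3D"], 0)
  expect_equal(sum(res2$bins$n), nrow(s2))

  expect_error(count_synergies(s2[-1, ]), "incomplete")
})

test_that("noise-free screens with known deltas count exactly the seeded synergies", {
  cfg <- generator_config(cell_lines = c("HCT-116", "HT-29"), formats = "2D",
                          drugs = c("5-FU", "OXA", "PAL", "PI"),
                          noise_sd = c("2D" = 0),
                          include_single_screen = FALSE,
                          include_death_readouts = FALSE,
                          readouts = "viability", seed = 10)
  cfg <- set_interaction(cfg, "5-FU", "OXA", -0.1)
  cfg <- set_interaction(cfg, "PAL", "PI", -0.05, cell_lines = "HT-29")
  cfg <- set_interaction(cfg, "OXA", "PI", 0.1)
  norm <- normalize_dataset(simulate_screen(cfg))
  summaries <- dplyr::bind_rows(lapply(
    assemble_dose_matrices(norm, "viability", 1), function(m) {
      summarize_synergy(score_matrix(m))
    }))
  res <- count_synergies(summaries)
  expect_equal(res$counts$n_synergistic, 2) # 5-FU+OXA and PAL+PI
  tt <- truth_table(cfg)
  joined <- dplyr::left_join(
    summaries, tt,
    by = c("cell_line", "culture_format", "combination"))
  expect_equal(joined$synergistic, joined$synergistic_true)
})
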