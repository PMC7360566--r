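test_that("pearson_r matches the product-moment formula and handles NAs", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -2 * (1:10) + 5)$r, -1)
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 100)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, oracle, tolerance = 1e-12)
  res <- pearson_r(c(x, NA), c(y, 1))
  expect_equal(res$n_used, 4)
  expect_equal(res$n_dropped, 1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("unique_calls is readout-exclusive set algebra on the design grid", {
  grid <- tidyr::expand_grid(cell_line = c("CL1", "CL2"),
                             combination = c("A + B", "A + C", "B + C"))
  calls_same <- dplyr::bind_rows(
    dplyr::mutate(grid[1:3, ], readout = "viability"),
    dplyr::mutate(grid[1:3, ], readout = "confluency"))
  res <- unique_calls(calls_same, grid)
  expect_equal(nrow(res$unique_calls), 0)
  expect_equal(res$totals$n_unique, c(0L, 0L))

  one <- tibble::tibble(
    readout = c("viability", "confluency"),
    cell_line = c("CL1", "CL1"),
    combination = c("A + B", "A + B"))
  one <- rbind(one, tibble::tibble(readout = "viability", cell_line = "CL2",
                                   combination = "B + C"))
  res2 <- unique_calls(one, grid)
  expect_equal(res2$unique_calls$combination, "B + C")
  expect_equal(res2$totals$n_unique[res2$totals$readout == "viability"], 1L)

  # constructed overlaps across 4 readouts vs brute-force set operations
  set.seed(17)
  big_grid <- tidyr::expand_grid(cell_line = paste0("CL", 1:3),
                                 combination = paste0("P", 1:21))
  keys <- paste(big_grid$cell_line, big_grid$combination)
  sets <- lapply(1:4, function(i) sample(keys, 20))
  calls <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(readout = paste0("R", i),
                   cell_line = sub(" .*", "", sets[[i]]),
                   combination = sub("^\\S+ ", "", sets[[i]]))
  }))
  res3 <- unique_calls(calls, big_grid)
  for (i in 1:4) {
    brute <- setdiff(sets[[i]], unlist(sets[-i]))
    got <- res3$totals$n_unique[res3$totals$readout == paste0("R", i)]
    expect_equal(got, length(brute))
  }
  # partition: unique calls plus shared calls reconstruct the union
  all_keys <- unique(unlist(sets))
  uniq_keys <- paste(res3$unique_calls$cell_line, res3$unique_calls$combination)
  shared <- names(which(table(unlist(lapply(sets, unique))) >= 2))
  expect_setequal(c(uniq_keys, shared), all_keys)

  expect_error(unique_calls(dplyr::mutate(one, cell_line = "CLX"), grid),
               "outside the design grid")
  expect_error(unique_calls(one[1, ], grid), "at least 2 readouts")
})

test_that("group comparisons are two-tailed t-tests with star thresholds", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "")

  set.seed(19)
  strong <- compare_groups(rnorm(20, 0), rnorm(20, 3))
  expect_equal(strong$stars, "***")
  expect_lt(strong$p_value, 0.001)
  expect_lt(strong$mean_difference, 0)

  # paired and unpaired tests agree in the direction of the difference
  a <- rnorm(10, 1)
  b <- rnorm(10, 0)
  expect_equal(sign(compare_groups(a, b, paired = TRUE)$mean_difference),
               sign(compare_groups(a, b, paired = FALSE)$mean_difference))
  expect_error(compare_groups(1:3, 1:4, paired = TRUE), "equal-length")
  expect_error(compare_groups(1, 1:3), "at least 2")
})

test_that("CV is the sample SD over the mean and is scale invariant", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(8, 12)), 2 * sqrt(2) / 10)
  x <- c(3, 5, 9, 11)
  expect_equal(cv(17.3 * x), cv(x), tolerance = 1e-12)
  expect_error(cv(c(-1, 1)), "zero mean")
  expect_error(cv(3), "at least 2")
})

test_that("per-condition CVs recover the generator noise level", {
  cfg <- generator_config(cell_lines = c("HCT-116", "HT-29"), formats = "2D",
                          drugs = c("5-FU", "OXA", "PAL", "PI"),
                          noise_sd = c("2D" = 0.1), n_tech = 4,
                          include_death_readouts = FALSE,
                          readouts = "viability", seed = 12)
  norm <- normalize_dataset(simulate_screen(cfg))
  tbl <- condition_cv(norm)
  expect_gt(nrow(tbl), 500)
  # sample SD of n = 4 normal draws underestimates sigma by c4 = E[s]/sigma
  c4 <- sqrt(2 / 3) * gamma(2) / gamma(1.5)
  expect_equal(mean(tbl$cv), 0.1 * c4, tolerance = 0.02)

  ov <- overall_cv(tbl)
  # brute-force group means
  brute <- as.numeric(tapply(tbl$cv, interaction(tbl$bio_rep, tbl$readout),
                             mean))
  expect_equal(sort(ov$cv_overall), sort(brute[!is.na(brute)]),
               tolerance = 1e-12)
  expect_equal(overall_cv(tbl[5, ])$cv_overall, tbl$cv[5])
  two <- tibble::tibble(bio_rep = 1L, readout = "viability", cv = c(0.1, 0.3))
  expect_equal(overall_cv(two)$cv_overall, 0.2)
})

test_that("replicate correlations: identical replicates give r = 1", {
  cfg <- small_config(seed = 14, noise_sd = 0, drugs = c("OXA", "PD"))
  norm <- normalize_dataset(simulate_screen(cfg))
  rc <- replicate_correlation(norm, "intra_screen")
  expect_equal(rc$pearson_r, 1, tolerance = 1e-12)
})

test_that("noise attenuates replicate correlation as predicted", {
  # attenuation oracle: r -> var(signal) / (var(signal) + var(noise))
  set.seed(23)
  truth <- runif(600, 0.1, 1)
  s_noise <- 0.05
  rep1 <- truth + rnorm(600, 0, s_noise)
  rep2 <- truth + rnorm(600, 0, s_noise)
  expected <- stats::var(truth) / (stats::var(truth) + s_noise^2)
  got <- pearson_r(rep1, rep2)$r
  # Fisher-z three-sigma band for n = 600
  z_half <- 3 / sqrt(600 - 3)
  expect_lt(abs(atanh(got) - atanh(expected)), z_half)
})

test_that("inter-screen correlation uses shared single-agent doses", {
  # combination doses are by design a subset of the single-screen series
  cfg <- generator_config(cell_lines = "HCT-116", formats = "2D",
                          drugs = c("OXA", "PD"), noise_sd = c("2D" = 0.02),
                          include_death_readouts = FALSE,
                          readouts = "viability", seed = 15)
  norm <- normalize_dataset(simulate_screen(cfg))
  rc <- replicate_correlation(norm, "inter_screen")
  expect_equal(rc$level, "inter_screen")
  expect_gt(rc$pearson_r, 0.9)
  expect_equal(rc$n_points, 8) # 2 drugs x 4 shared doses

  # disjoint dose sets: no overlap -> error
  cfg2 <- cfg
  cfg2$single_doses <- c(0.011, 0.111, 1.11, 11.1)
  norm2 <- normalize_dataset(simulate_screen(cfg2))
  expect_error(replicate_correlation(norm2, "inter_screen"), "shared")
})
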