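#' Configuration for the synthetic screen generator
#'
#' Builds a generator configuration emulating the study design: 3 colorectal
#' cancer cell lines x 2 culture formats, a 7-drug panel, an 8-dose
#' single-agent screen over 0.01-20 uM, all 21 pairwise 5 x 5 combination
#' matrices (vehicle + 4 non-zero doses per drug), 4 technical x 2 biological
#' replicates, and a 48 h endpoint. Ground truth is a Hill (4PL) viability
#' curve per (drug, cell line, format) plus an additive Bliss deviation
#' `delta` per (pair, cell line, format): the true combination viability is
#' `clamp(V_A * V_B + delta, 0, 1.5)`, so the ground-truth Bliss excess
#' equals `delta` wherever clamping is inactive.
#'
#' Default Hill parameters are fixed, field-realistic values: the MEK
#' inhibitor PD is the most potent drug, followed by the TAK1 inhibitor 5Z;
#' spheroids (3D) are slightly less sensitive than monolayers except to MEK
#' inhibition, and carry higher multiplicative noise. Raw signals are
#' `scale * V^exponent * (1 + eps)` with `eps ~ N(0, noise_sd[format])`:
#' viability is linear in V (ATP luminescence), confluency scales as
#' `V^confluency_exponent` (percent area), and spheroid size as
#' `V^size_exponent` (diameter of a volume roughly proportional to viable
#' cell count). Cell-death readouts stay near baseline unless the drug is
#' flagged apoptotic, in which case the signal rises with effect.
#'
#' @param cell_lines,formats character vectors of the design.
#' @param drugs drug panel (abbreviations).
#' @param interactions tibble with columns `drug_a`, `drug_b`, `cell_line`,
#'   `culture_format`, `delta`; pairs absent from it have `delta = 0`. Use
#'   [set_interaction()] to build it incrementally.
#' @param n_tech,n_bio technical and biological replicate counts.
#' @param noise_sd named numeric: multiplicative noise sd per format.
#' @param vehicle_signal raw-scale viability baseline (luminescence counts);
#'   the default is a power of two so that zero-noise normalization is exact
#'   in floating point.
#' @param confluency_exponent,size_exponent coupling of imaging readouts to
#'   true viability.
#' @param apoptosis_drugs drugs that induce a detectable cell-death signal.
#' @param single_doses single-agent screen doses in micromolar.
#' @param timepoint endpoint in hours.
#' @param include_single_screen generate the 8-dose single-agent screen.
#' @param include_death_readouts generate CellTox/NucView-style death signals
#'   for the 2D single-agent screen.
#' @param readouts growth readouts to generate (viability always; confluency
#'   only for 2D, spheroid_size only for 3D).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(cell_lines = c("HCT-116", "HT-29", "SW-620"),
                             formats = c("2D", "3D"),
                             drugs = c("5-FU", "5Z", "OLA", "OXA",
                                       "PAL", "PD", "PI"),
                             interactions = NULL,
                             n_tech = 4, n_bio = 2,
                             noise_sd = c("2D" = 0.05, "3D" = 0.08),
                             vehicle_signal = 8192,
                             confluency_exponent = 0.8,
                             size_exponent = 1 / 3,
                             apoptosis_drugs = "5Z",
                             single_doses = 10^seq(log10(0.01), log10(20),
                                                   length.out = 8),
                             timepoint = 48,
                             include_single_screen = TRUE,
                             include_death_readouts = TRUE,
                             readouts = c("viability", "confluency",
                                          "spheroid_size"),
                             seed = 1L) {
  if (anyDuplicated(drugs)) abort("invalid config field 'drugs': duplicates")
  if (n_tech < 1 || n_bio < 1) abort("invalid config field 'n_tech'/'n_bio'")
  if (any(noise_sd < 0)) abort("invalid config field 'noise_sd': negative")
  if (!all(formats %in% names(noise_sd))) {
    abort("invalid config field 'noise_sd': must name every format")
  }
  if (any(single_doses <= 0)) {
    abort("invalid config field 'single_doses': non-positive dose")
  }
  if (vehicle_signal <= 0) abort("invalid config field 'vehicle_signal'")

  hill <- .default_hill_params(drugs, cell_lines, formats)
  combo_doses <- .default_combo_doses(drugs, single_doses)
  if (is.null(interactions)) {
    interactions <- tibble(drug_a = character(), drug_b = character(),
                           cell_line = character(),
                           culture_format = character(), delta = double())
  }
  structure(
    list(cell_lines = cell_lines, formats = formats, drugs = drugs,
         hill_params = hill, combo_doses = combo_doses,
         interactions = interactions,
         n_tech = as.integer(n_tech), n_bio = as.integer(n_bio),
         noise_sd = noise_sd, vehicle_signal = vehicle_signal,
         confluency_exponent = confluency_exponent,
         size_exponent = size_exponent,
         apoptosis_drugs = apoptosis_drugs,
         single_doses = single_doses, timepoint = timepoint,
         include_single_screen = include_single_screen,
         include_death_readouts = include_death_readouts,
         readouts = readouts, seed = as.integer(seed)),
    class = "generator_config")
}

# fixed ground-truth Hill parameters: potency ordering PD > 5Z > PI > OXA >
# PAL > 5-FU > OLA, mild per-cell-line potency shifts, spheroids less
# sensitive except to the MEK inhibitor
.default_hill_params <- function(drugs, cell_lines, formats) {
  base <- tibble(
    drug = c("PD", "5Z", "PI", "OXA", "5-FU", "PAL", "OLA"),
    ec50 = c(0.03, 0.12, 0.35, 1.5, 4.0, 2.5, 12.0),
    lower = c(0.15, 0.20, 0.25, 0.20, 0.35, 0.45, 0.70),
    hill = c(1.6, 1.8, 1.4, 1.2, 1.0, 1.3, 1.0)
  )
  extra <- setdiff(drugs, base$drug)
  if (length(extra) > 0) {
    base <- bind_rows(base, tibble(drug = extra, ec50 = 1, lower = 0.3,
                                   hill = 1.2))
  }
  base <- filter(base, .data$drug %in% drugs)
  cl_factor <- setNames(rep(c(1.0, 1.6, 0.8), length.out = length(cell_lines)),
                        cell_lines)
  grid <- tidyr::expand_grid(base, cell_line = cell_lines,
                             culture_format = formats)
  grid |>
    mutate(
      fmt_factor = ifelse(.data$culture_format == "3D",
                          ifelse(.data$drug == "PD", 0.6, 1.25), 1.0),
      ec50 = .data$ec50 * cl_factor[.data$cell_line] * .data$fmt_factor,
      upper = 1.0
    ) |>
    select("drug", "cell_line", "culture_format", "upper", "lower",
           "ec50", "hill")
}

# combination doses are 4 of the 8 single-screen doses per drug (as in the
# screen design, where single-agent response guided combination dose
# selection): a 4-dose window of the log-spaced series with the dose nearest
# the drug's base EC50 third in the window
.default_combo_doses <- function(drugs, single_doses = 10^seq(log10(0.01),
                                                              log10(20),
                                                              length.out = 8)) {
  base_ec50 <- c("PD" = 0.03, "5Z" = 0.12, "PI" = 0.35, "OXA" = 1.5,
                 "5-FU" = 4.0, "PAL" = 2.5, "OLA" = 12.0)
  ec <- ifelse(drugs %in% names(base_ec50), base_ec50[drugs], 1)
  tibble(drug = drugs,
         doses = purrr::map(ec, function(e) {
           k <- which.min(abs(log(single_doses) - log(e)))
           start <- min(max(k - 2, 1), length(single_doses) - 3)
           single_doses[start:(start + 3)]
         }))
}

#' Add an injected Bliss deviation to a generator configuration
#'
#' @param config a [generator_config()].
#' @param drug_x,drug_y the pair (order irrelevant).
#' @param delta Bliss deviation on the viability scale; negative = synergy.
#' @param cell_lines,formats contexts to apply it in (default: all).
#' @return The updated config.
#' @export
set_interaction <- function(config, drug_x, drug_y, delta,
                            cell_lines = NULL, formats = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cell_lines <- cell_lines %||% config$cell_lines
  formats <- formats %||% config$formats
  add <- tidyr::expand_grid(cell_line = cell_lines,
                            culture_format = formats) |>
    mutate(drug_a = min(drug_x, drug_y), drug_b = max(drug_x, drug_y),
           delta = delta)
  config$interactions <- bind_rows(config$interactions, add) |>
    distinct(.data$drug_a, .data$drug_b, .data$cell_line,
             .data$culture_format, .keep_all = TRUE)
  config
}

#' An example synergy landscape for demonstrations
#'
#' A generator configuration with a realistic mix of injected interactions:
#' synergy for the PI3K + MEK and PI3K + TAK1 inhibitor pairs, chemotherapy
#' synergy (5-FU + oxaliplatin) in monolayers, MEK-inhibitor combinations
#' that are more synergistic in spheroids, and a majority of non-interacting
#' pairs — more synergistic pairs in 2D than in 3D overall.
#'
#' @param seed integer seed.
#' @param ... passed to [generator_config()].
#' @return A `generator_config`.
#' @export
example_screen_config <- function(seed = 1L, ...) {
  cfg <- generator_config(seed = seed, ...)
  cfg <- set_interaction(cfg, "PI", "PD", -0.15)
  cfg <- set_interaction(cfg, "PI", "5Z", -0.12, formats = "2D")
  cfg <- set_interaction(cfg, "PI", "5Z", -0.10,
                         cell_lines = "HCT-116", formats = "3D")
  cfg <- set_interaction(cfg, "5-FU", "OXA", -0.08, formats = "2D")
  cfg <- set_interaction(cfg, "PAL", "5Z", -0.10,
                         cell_lines = "HCT-116", formats = "2D")
  cfg <- set_interaction(cfg, "OXA", "PAL", -0.08,
                         cell_lines = "HT-29", formats = "2D")
  cfg <- set_interaction(cfg, "PD", "PAL", -0.10,
                         cell_lines = "SW-620", formats = "2D")
  cfg <- set_interaction(cfg, "PD", "OXA", -0.05,
                         cell_lines = "HCT-116", formats = "2D")
  cfg <- set_interaction(cfg, "PD", "OXA", -0.12,
                         cell_lines = c("HCT-116", "HT-29"), formats = "3D")
  cfg <- set_interaction(cfg, "5-FU", "OLA", -0.08,
                         cell_lines = c("HCT-116", "SW-620"), formats = "3D")
  cfg <- set_interaction(cfg, "5-FU", "PD", -0.10,
                         cell_lines = "HCT-116", formats = "3D")
  cfg <- set_interaction(cfg, "OLA", "PD", -0.08,
                         cell_lines = c("HCT-116", "SW-620"), formats = "3D")
  # one mildly antagonistic pair
  cfg <- set_interaction(cfg, "5-FU", "PAL", 0.08, formats = "2D")
  cfg
}

# true single-agent viability from the ground-truth Hill curve
.hill_viability <- function(dose, upper, lower, ec50, hill) {
  ifelse(dose == 0, upper,
         lower + (upper - lower) / (1 + (dose / ec50)^hill))
}

# look up hill params as vectors aligned with a well table
.join_hill <- function(df, hill_params, drug_col, dose_col, out_col) {
  hp <- hill_params
  names(hp)[names(hp) == "drug"] <- drug_col
  df <- left_join(df, hp, by = c(drug_col, "cell_line", "culture_format"))
  v <- ifelse(df[[drug_col]] == "" | df[[dose_col]] == 0,
              1.0,
              .hill_viability(df[[dose_col]], df$upper, df$lower,
                              df$ec50, df$hill))
  # drugless slots and vehicle contribute no inhibition
  v[df[[drug_col]] == ""] <- 1.0
  df[[out_col]] <- v
  df[, setdiff(names(df), c("upper", "lower", "ec50", "hill"))]
}

#' Simulate a full drug-combination screen with known ground truth
#'
#' Generates raw per-well signals for the combination screen (all pairwise
#' 5 x 5 matrices, `n_tech` technical x `n_bio` biological replicates) and,
#' optionally, the 8-dose single-agent screen, for every cell line and
#' culture format in the configuration. Each combination plate holds one
#' (cell line, format, pair, biological replicate): 96 treatment wells,
#' 16 vehicle wells (the four double-vehicle matrix wells plus 12 dedicated
#' vehicle wells) and 8 positive-control wells. Deterministic given
#' `config$seed`.
#'
#' @param config a [generator_config()].
#' @return A [screen_dataset()] of raw signals, with the design (including
#'   the ground-truth interaction table) in `$design`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$seed)

  pairs <- enumerate_pairs(config$drugs)
  dose_of <- setNames(config$combo_doses$doses, config$combo_doses$drug)

  # ---- combination screen: physical wells -------------------------------
  cell_grid <- purrr::pmap(pairs, function(drug_a, drug_b, combination) {
    g <- tidyr::expand_grid(dose_a = c(0, dose_of[[drug_a]]),
                            dose_b = c(0, dose_of[[drug_b]]))
    g$drug_a <- drug_a
    g$drug_b <- drug_b
    g$combination <- combination
    g
  })
  cell_grid <- bind_rows(cell_grid)

  combo <- tidyr::expand_grid(
    cell_line = config$cell_lines,
    culture_format = config$formats,
    bio_rep = seq_len(config$n_bio),
    cell_grid,
    tech_rep = seq_len(config$n_tech)
  ) |>
    mutate(
      role = ifelse(.data$dose_a == 0 & .data$dose_b == 0,
                    "vehicle", "treatment"),
      drug_a = ifelse(.data$role == "vehicle", "", .data$drug_a),
      drug_b = ifelse(.data$role == "vehicle", "", .data$drug_b),
      plate_id = sprintf("COMBO_%s_%s_b%d_%s", .data$cell_line,
                         .data$culture_format, .data$bio_rep,
                         gsub(" ", "", .data$combination)),
      screen = "combination"
    )

  # extra vehicle and positive-control wells per combination plate
  plates <- distinct(combo, .data$plate_id, .data$cell_line,
                     .data$culture_format, .data$bio_rep, .data$combination)
  extra <- tidyr::expand_grid(plates, slot = 1:20) |>
    mutate(
      role = ifelse(.data$slot <= 12, "vehicle", "positive_control"),
      drug_a = ifelse(.data$role == "positive_control",
                      ifelse(.data$slot %% 2 == 0, "staurosporine",
                             "digitonin"), ""),
      drug_b = "", dose_a = 0, dose_b = 0,
      tech_rep = .data$slot, screen = "combination"
    ) |>
    select(-"slot")
  combo <- bind_rows(combo, extra)

  # ---- single-agent screen ---------------------------------------------
  if (config$include_single_screen) {
    single <- tidyr::expand_grid(
      cell_line = config$cell_lines,
      culture_format = config$formats,
      drug_a = config$drugs,
      dose_a = config$single_doses,
      tech_rep = seq_len(config$n_tech)
    ) |>
      mutate(drug_b = "", dose_b = 0, bio_rep = 1L, role = "treatment",
             combination = NA_character_,
             plate_id = sprintf("SINGLE_%s_%s", .data$cell_line,
                                .data$culture_format),
             screen = "single")
    splates <- distinct(single, .data$plate_id, .data$cell_line,
                        .data$culture_format)
    sextra <- tidyr::expand_grid(splates, slot = 1:24) |>
      mutate(
        role = ifelse(.data$slot <= 16, "vehicle", "positive_control"),
        drug_a = ifelse(.data$role == "positive_control",
                        ifelse(.data$slot %% 2 == 0, "staurosporine",
                               "digitonin"), ""),
        drug_b = "", dose_a = 0, dose_b = 0, bio_rep = 1L,
        combination = NA_character_,
        tech_rep = .data$slot, screen = "single"
      ) |>
      select(-"slot")
    wells <- bind_rows(combo, bind_rows(single, sextra))
  } else {
    wells <- combo
  }

  # ---- ground-truth viability ------------------------------------------
  wells <- .join_hill(wells, config$hill_params, "drug_a", "dose_a", "v_a")
  wells <- .join_hill(wells, config$hill_params, "drug_b", "dose_b", "v_b")
  ia <- config$interactions
  if (nrow(ia) > 0) {
    ia <- mutate(ia, combination = pair_key(.data$drug_a, .data$drug_b)) |>
      select("combination", "cell_line", "culture_format", "delta")
    wells <- left_join(wells, ia,
                       by = c("combination", "cell_line", "culture_format"))
  } else {
    wells$delta <- NA_real_
  }
  wells <- mutate(
    wells,
    delta = ifelse(is.na(.data$delta), 0, .data$delta),
    v_true = dplyr::case_when(
      role == "positive_control" ~ 0.02,
      role == "vehicle" ~ 1.0,
      dose_a > 0 & dose_b > 0 ~ .clamp(v_a * v_b + delta, 0, 1.5),
      TRUE ~ v_a * v_b
    )
  )

  # ---- well coordinates, stable order, readouts ------------------------
  wells <- wells |>
    arrange(.data$plate_id, .data$role, .data$drug_a, .data$drug_b,
            .data$dose_a, .data$dose_b, .data$tech_rep) |>
    group_by(.data$plate_id) |>
    mutate(well = .well_ids(n())[row_number()]) |>
    ungroup()

  growth_readouts <- intersect(config$readouts, c("viability", "confluency",
                                                  "spheroid_size"))
  readout_tbl <- bind_rows(
    tibble(readout = "viability", fmt = c("2D", "3D")),
    tibble(readout = "confluency", fmt = "2D"),
    tibble(readout = "spheroid_size", fmt = "3D")
  ) |>
    filter(.data$readout %in% growth_readouts)
  meas <- dplyr::inner_join(wells, readout_tbl,
                            by = c(culture_format = "fmt"),
                            relationship = "many-to-many")
  if (config$include_death_readouts && config$include_single_screen) {
    death <- filter(wells, .data$screen == "single",
                    .data$culture_format == "2D")
    meas <- bind_rows(meas,
                      mutate(death, readout = "celltox"),
                      mutate(death, readout = "nucview"))
  }

  # power-of-two raw scales: scaling and vehicle division are then exact in
  # floating point, so a zero-noise screen normalizes to the true viability
  # bit-for-bit and the Bliss null scores exactly zero
  scale_of <- c(viability = config$vehicle_signal, confluency = 64,
                spheroid_size = 512, celltox = 128, nucview = 128)
  exp_of <- c(viability = 1, confluency = config$confluency_exponent,
              spheroid_size = config$size_exponent)
  meas <- meas |>
    arrange(.data$plate_id, .data$well, .data$readout) |>
    mutate(
      .is_death = .data$readout %in% c("celltox", "nucview"),
      .apopt = .data$role == "treatment" &
        (.data$drug_a %in% config$apoptosis_drugs |
           .data$drug_b %in% config$apoptosis_drugs),
      .mu = ifelse(
        .data$.is_death,
        scale_of[.data$readout] *
          ifelse(.data$.apopt | .data$role == "positive_control",
                 1 + 4 * (1 - .clamp(.data$v_true, 0, 1)), 1),
        scale_of[.data$readout] * .data$v_true^exp_of[.data$readout]),
      value = pmax(.data$.mu *
                     (1 + rnorm(n(), 0, config$noise_sd[.data$culture_format])),
                   0),
      timepoint = config$timepoint,
      tech_rep = as.integer(.data$tech_rep),
      bio_rep = as.integer(.data$bio_rep)
    )

  records <- select(meas, "plate_id", "well", "cell_line", "culture_format",
                    "role", "drug_a", "dose_a", "drug_b", "dose_b",
                    "readout", "timepoint", "tech_rep", "bio_rep", "value")
  screen_dataset(records, design = list(
    cell_lines = config$cell_lines, formats = config$formats,
    drugs = config$drugs, pairs = pairs,
    combo_doses = config$combo_doses, single_doses = config$single_doses,
    n_tech = config$n_tech, n_bio = config$n_bio,
    interactions = config$interactions, seed = config$seed
  ))
}

#' Ground-truth expectations for a generator configuration
#'
#' Closed-form (no sampling) per (cell line, format, pair) expectations at
#' zero noise: the injected deviation `delta`, the true matrix-mean Bliss
#' excess (which differs from `delta` only where the combination viability
#' clamps at 0), the expected synergy flag, and the expected count of
#' synergistically effective dose pairs (excess < 0 and viability <= the
#' effectiveness threshold).
#'
#' @param config a [generator_config()].
#' @param effectiveness_threshold viability cut (default 0.5).
#' @return Tibble, one row per (cell_line, culture_format, combination).
#' @export
truth_table <- function(config, effectiveness_threshold = 0.5) {
  stopifnot(inherits(config, "generator_config"))
  pairs <- enumerate_pairs(config$drugs)
  dose_of <- setNames(config$combo_doses$doses, config$combo_doses$drug)
  hp <- config$hill_params
  ia <- config$interactions
  if (nrow(ia) > 0) {
    ia <- mutate(ia, combination = pair_key(.data$drug_a, .data$drug_b))
  }
  grid <- tidyr::expand_grid(pairs, cell_line = config$cell_lines,
                             culture_format = config$formats)
  purrr::pmap(grid, function(drug_a, drug_b, combination, cell_line,
                             culture_format) {
    pa <- filter(hp, .data$drug == drug_a, .data$cell_line == !!cell_line,
                 .data$culture_format == !!culture_format)
    pb <- filter(hp, .data$drug == drug_b, .data$cell_line == !!cell_line,
                 .data$culture_format == !!culture_format)
    va <- .hill_viability(dose_of[[drug_a]], pa$upper, pa$lower, pa$ec50,
                          pa$hill)
    vb <- .hill_viability(dose_of[[drug_b]], pb$upper, pb$lower, pb$ec50,
                          pb$hill)
    delta <- 0
    if (nrow(ia) > 0) {
      hit <- filter(ia, .data$combination == !!combination,
                    .data$cell_line == !!cell_line,
                    .data$culture_format == !!culture_format)
      if (nrow(hit) > 0) delta <- hit$delta[[1]]
    }
    v_obs <- .clamp(outer(va, vb) + delta, 0, 1.5)
    excess <- v_obs - outer(.clamp(va, 0, 1), .clamp(vb, 0, 1))
    tibble(
      cell_line = cell_line, culture_format = culture_format,
      drug_a = drug_a, drug_b = drug_b, combination = combination,
      delta = delta,
      mean_excess_true = mean(excess),
      mean_viability_true = mean(v_obs),
      synergistic_true = mean(excess) < 0,
      n_effective_true = sum(excess < 0 & v_obs <= effectiveness_threshold)
    )
  }) |>
    bind_rows()
}
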