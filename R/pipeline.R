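#' Pipeline run configuration
#'
#' Bundles the inputs and thresholds of a full analysis run. All thresholds
#' carry the screen's defaults (synergy at Bliss excess 0, effectiveness at
#' viability 0.5, significance at alpha 0.05) and are surfaced here so
#' sensitivity analyses are one argument away.
#'
#' @param dataset a [screen_dataset()] (takes precedence over `input_csv`).
#' @param input_csv path to a tidy measurement CSV (see [read_screen_csv()]).
#' @param out_dir output directory for the report bundle; created if needed.
#'   `NULL` keeps everything in memory.
#' @param readouts readouts to score for synergy; default: every readout with
#'   combination wells.
#' @param synergy_threshold Bliss-excess cut for a synergy call (strictly
#'   below; default 0).
#' @param effectiveness_threshold viability cut for the effectiveness gate.
#' @param alpha significance level for group comparisons.
#' @param bin_edges Bliss-excess histogram bin edges.
#' @param ic_level inhibition fraction for the censored IC (default 0.2).
#' @param dose_range tested single-agent dose range in micromolar.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dataset = NULL, input_csv = NULL, out_dir = NULL,
                       readouts = NULL, synergy_threshold = 0,
                       effectiveness_threshold = 0.5, alpha = 0.05,
                       bin_edges = c(-0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2),
                       ic_level = 0.2, dose_range = c(0.01, 20)) {
  if (is.null(dataset) && is.null(input_csv)) {
    abort("provide a dataset or an input_csv path")
  }
  stopifnot(is.finite(synergy_threshold), is.finite(effectiveness_threshold),
            is.finite(alpha))
  structure(list(dataset = dataset, input_csv = input_csv, out_dir = out_dir,
                 readouts = readouts, synergy_threshold = synergy_threshold,
                 effectiveness_threshold = effectiveness_threshold,
                 alpha = alpha, bin_edges = bin_edges, ic_level = ic_level,
                 dose_range = dose_range),
            class = "run_config")
}

#' Run the full screen-analysis pipeline
#'
#' Executes normalize -> assemble -> single-agent dose-response -> Bliss
#' synergy scoring (per biological replicate, then replicate-averaged) ->
#' agreement and reproducibility metrics, and (when `out_dir` is set) writes
#' tidy CSV reports, a JSON manifest and a plain-text run log. Re-running
#' with identical inputs and configuration reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, the report bundle: a list with `normalized`,
#'   `dose_response`, `synergy_summary`, `synergy_dose_level`,
#'   `synergy_counts`, `excess_bins`, `format_comparison` (2D vs 3D
#'   per-combination viability t-tests, when both formats and >= 2 biological
#'   replicates are present), `callsets`, `unique_calls`, `cv_by_condition`,
#'   `cv_overall`, `replicate_correlation` and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  ds <- config$dataset %||% stage("read", read_screen_csv(config$input_csv))
  say("loaded %d well records", nrow(as_screen_records(ds)))

  norm <- stage("normalize", normalize_dataset(ds))
  say("normalized to per-plate vehicle controls")

  # single-agent dose-response per readout that has single-agent wells
  sa_readouts <- norm |>
    filter(.data$role == "treatment", .data$drug_b == "",
           .data$readout %in% c("viability", "confluency",
                                "spheroid_size")) |>
    pull(.data$readout) |>
    unique()
  dr <- NULL
  if (length(sa_readouts) > 0) {
    dr <- stage("dose_response", bind_rows(purrr::map(
      sa_readouts, function(ro) {
        summarize_dose_response(norm, readout = ro, level = config$ic_level,
                                dose_range = config$dose_range)
      })))
    say("fitted %d single-agent dose-response curves", nrow(dr))
  }

  # synergy scoring per (readout, bio rep), then replicate averaging
  combo <- filter(norm, .data$role == "treatment", .data$drug_a != "",
                  .data$drug_b != "")
  readouts <- config$readouts %||% sort(unique(combo$readout))
  bio_reps <- sort(unique(combo$bio_rep))
  summaries <- list()
  dose_level <- list()
  rep_viability <- list()
  n_missing_cells <- 0
  for (ro in readouts) {
    grids_by_key <- list()
    for (br in bio_reps) {
      if (nrow(filter(combo, .data$readout == ro, .data$bio_rep == br)) == 0) next
      to_log <- function(w) {
        n_missing_cells <<- n_missing_cells + grepl("missing", conditionMessage(w))
        say("warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
      mats <- stage("assemble", withCallingHandlers(
        assemble_dose_matrices(norm, readout = ro, bio_rep = br),
        warning = to_log))
      grids <- withCallingHandlers(purrr::map(mats, score_matrix),
                                   warning = to_log)
      for (g in grids) {
        key <- paste(g$cell_line, g$culture_format,
                     pair_key(g$drug_a, g$drug_b), sep = "|")
        grids_by_key[[key]] <- c(grids_by_key[[key]], list(g))
        rep_viability[[paste(ro, key, br)]] <- tibble(
          readout = ro, cell_line = g$cell_line,
          culture_format = g$culture_format,
          combination = pair_key(g$drug_a, g$drug_b),
          bio_rep = br,
          mean_viability = mean(g$observed, na.rm = TRUE))
      }
    }
    for (key in names(grids_by_key)) {
      avg <- stage("synergy", average_replicates(grids_by_key[[key]]))
      summaries[[paste(ro, key)]] <-
        summarize_synergy(avg, config$effectiveness_threshold)
      k <- length(avg$doses_a)
      m <- length(avg$doses_b)
      dose_level[[paste(ro, key)]] <- tibble(
        cell_line = avg$cell_line, culture_format = avg$culture_format,
        drug_a = avg$drug_a, drug_b = avg$drug_b,
        combination = pair_key(avg$drug_a, avg$drug_b), readout = ro,
        dose_a = rep(avg$doses_a, times = m),
        dose_b = rep(avg$doses_b, each = k),
        excess = as.vector(avg$excess),
        sd_excess = as.vector(avg$sd_excess),
        observed = as.vector(avg$observed),
        expected = as.vector(avg$expected),
        n_rep = as.vector(avg$n_rep)
      )
    }
  }
  synergy_summary <- bind_rows(summaries)
  synergy_dose_level <- bind_rows(dose_level)
  say("scored %d replicate-averaged matrices (%d readouts)",
      nrow(synergy_summary), length(readouts))

  counts <- stage("synergy", purrr::map(
    split(synergy_summary, synergy_summary$readout),
    count_synergies, bin_edges = config$bin_edges))
  synergy_counts <- bind_rows(
    purrr::imap(counts, function(x, ro) mutate(x$counts, readout = ro)))
  excess_bins <- bind_rows(
    purrr::imap(counts, function(x, ro) mutate(x$bins, readout = ro)))

  # cross-readout agreement: synergy calls per (readout, format)
  callsets <- synergy_summary |>
    mutate(readout_format = paste(.data$readout, .data$culture_format)) |>
    filter(.data$synergistic) |>
    select(readout = "readout_format", "cell_line", "combination")
  grid <- distinct(synergy_summary, .data$cell_line, .data$combination)
  uc <- NULL
  if (length(unique(callsets$readout)) >= 2) {
    uc <- stage("agreement", unique_calls(callsets, grid))
  }

  # 2D vs 3D sensitivity: unpaired two-tailed t-test on per-replicate
  # matrix-mean viabilities, per cell line and combination
  rep_via <- bind_rows(rep_viability)
  format_comparison <- NULL
  if (all(c("2D", "3D") %in% rep_via$culture_format) &&
      length(bio_reps) >= 2) {
    format_comparison <- rep_via |>
      filter(.data$readout == "viability") |>
      group_by(.data$cell_line, .data$combination) |>
      summarise(
        mean_2d = mean(.data$mean_viability[.data$culture_format == "2D"]),
        mean_3d = mean(.data$mean_viability[.data$culture_format == "3D"]),
        .test = list(compare_groups(
          .data$mean_viability[.data$culture_format == "2D"],
          .data$mean_viability[.data$culture_format == "3D"])),
        .groups = "drop") |>
      mutate(p_value = vapply(.data$.test, `[[`, double(1), "p_value"),
             stars = vapply(.data$.test, `[[`, character(1), "stars")) |>
      select(-".test")
  }

  # reproducibility
  cv_tbl <- stage("repro", condition_cv(norm))
  cv_all <- overall_cv(cv_tbl)
  rc <- list()
  if (length(bio_reps) >= 2) {
    rc$intra <- stage("repro", replicate_correlation(norm, "intra_screen"))
  }
  has_single <- any(norm$role == "treatment" & norm$drug_b == "")
  if (has_single) {
    rc$inter <- tryCatch(replicate_correlation(norm, "inter_screen"),
                         error = function(e) NULL)
  }
  repro <- bind_rows(rc)
  say("reproducibility: %d condition CVs, %d correlation strata",
      nrow(cv_tbl), nrow(repro))

  bundle <- list(
    normalized = norm, dose_response = dr,
    synergy_summary = synergy_summary,
    synergy_dose_level = synergy_dose_level,
    synergy_counts = synergy_counts, excess_bins = excess_bins,
    format_comparison = format_comparison,
    callsets = callsets,
    unique_calls = if (!is.null(uc)) uc$unique_calls else NULL,
    unique_call_totals = if (!is.null(uc)) uc$totals else NULL,
    cv_by_condition = cv_tbl, cv_overall = cv_all,
    replicate_correlation = repro,
    n_missing_cell_warnings = n_missing_cells,
    config = config, log = log_lines
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      if (!is.null(x) && nrow(x) > 0) {
        readr::write_csv(x, file.path(config$out_dir, paste0(name, ".csv")))
      }
    }
    wr(norm, "normalized")
    wr(dr, "dose_response")
    wr(select(synergy_summary, -"effective_doses"), "synergy_summary")
    wr(synergy_dose_level, "synergy_dose_level")
    wr(synergy_counts, "synergy_counts")
    wr(mutate(excess_bins, bin = as.character(.data$bin)), "excess_bins")
    wr(format_comparison, "format_comparison")
    wr(callsets, "callsets")
    wr(bundle$unique_call_totals, "unique_call_totals")
    wr(cv_tbl, "cv_by_condition")
    wr(cv_all, "cv_overall")
    wr(repro, "replicate_correlation")
    manifest <- list(
      package = "synscreen",
      version = as.character(utils::packageVersion("synscreen")),
      thresholds = list(synergy = config$synergy_threshold,
                        effectiveness = config$effectiveness_threshold,
                        alpha = config$alpha),
      readouts = readouts,
      n_records = nrow(as_screen_records(ds)),
      n_matrices = nrow(synergy_summary),
      missing_cell_warnings = n_missing_cells
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  invisible(bundle)
}

#' Design-count and synergy-count summary of a pipeline run
#'
#' Per culture format and readout: the total number of combination dose
#' points in the design (pairs x interior dose pairs x cell lines, derived
#' from the scored matrices, never hard-coded), how many show Bliss excess
#' below 0 (with the fraction), how many combinations are synergistic in at
#' least one cell line, and the combinations ranked by number of
#' synergistically effective doses.
#'
#' @param bundle result of [run_pipeline()].
#' @return List with `dose_points` (per format/readout totals and negative-
#'   excess counts and fractions), `synergistic_combinations`, and
#'   `effective_ranking` (combinations with at least one synergistically
#'   effective dose, most first).
#' @export
report_counts <- function(bundle) {
  dl <- bundle$synergy_dose_level
  if (is.null(dl) || nrow(dl) == 0) abort("empty bundle: no synergy output")
  dose_points <- dl |>
    filter(.data$dose_a > 0, .data$dose_b > 0) |>
    group_by(.data$readout, .data$culture_format) |>
    summarise(
      n_dose_points = n(),
      n_excess_negative = sum(.data$excess < 0, na.rm = TRUE),
      n_missing = sum(is.na(.data$excess)),
      fraction_negative = .data$n_excess_negative / .data$n_dose_points,
      .groups = "drop")
  ranking <- bundle$synergy_summary |>
    filter(.data$n_effective > 0) |>
    arrange(.data$readout, .data$culture_format,
            dplyr::desc(.data$n_effective)) |>
    select("readout", "culture_format", "cell_line", "combination",
           "n_effective", "mean_excess", "mean_viability")
  list(dose_points = dose_points,
       synergistic_combinations = bundle$synergy_counts,
       effective_ranking = ranking)
}
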