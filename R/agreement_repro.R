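#' Pearson correlation with pairwise-complete handling
#'
#' Standard product-moment correlation; pairs with any missing member are
#' dropped and the number of dropped pairs reported.
#'
#' @param x,y paired numeric vectors (at least 3 complete pairs, non-zero
#'   variance in both).
#' @return List with `r`, `n_used`, `n_dropped`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must be paired (equal length)")
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance: correlation undefined")
  }
  list(r = stats::cor(x, y), n_used = length(x), n_dropped = n_dropped)
}

#' Synergy calls unique to each readout
#'
#' Given synergy call sets from several readouts over the same design grid of
#' (cell line, combination) conditions, returns for each readout the calls
#' made by that readout and no other, plus call totals.
#'
#' @param calls tibble with columns `readout`, `cell_line`, `combination`,
#'   one row per synergistic call (at least 2 distinct readouts).
#' @param grid design grid tibble with columns `cell_line`, `combination`;
#'   every call must lie on it.
#' @return List with `unique_calls` (tibble readout / cell_line /
#'   combination of readout-exclusive calls) and `totals` (per readout:
#'   `n_calls`, `n_unique`).
#' @export
unique_calls <- function(calls, grid) {
  stopifnot(all(c("readout", "cell_line", "combination") %in% names(calls)),
            all(c("cell_line", "combination") %in% names(grid)))
  readouts <- unique(calls$readout)
  if (length(readouts) < 2) abort("need call sets from at least 2 readouts")
  off <- dplyr::anti_join(calls, grid, by = c("cell_line", "combination"))
  if (nrow(off) > 0) {
    abort(paste0("call(s) outside the design grid: ",
                 paste(utils::head(paste(off$readout, off$cell_line,
                                         off$combination), 5),
                       collapse = "; ")))
  }
  key <- function(df) paste(df$cell_line, df$combination, sep = "\r")
  uniq <- purrr::map(readouts, function(ro) {
    mine <- filter(calls, .data$readout == ro)
    others <- filter(calls, .data$readout != ro)
    filter(mine, !(key(mine) %in% key(others)))
  })
  unique_tbl <- bind_rows(uniq)
  totals <- tibble(readout = readouts) |>
    left_join(count(calls, .data$readout, name = "n_calls"), by = "readout") |>
    left_join(count(unique_tbl, .data$readout, name = "n_unique"),
              by = "readout") |>
    mutate(n_calls = dplyr::coalesce(.data$n_calls, 0L),
           n_unique = dplyr::coalesce(.data$n_unique, 0L))
  list(unique_calls = unique_tbl, totals = totals)
}

#' Two-tailed t-test between two groups with significance stars
#'
#' Two-tailed Student's t-test (Welch by default; set `var_equal = TRUE` for
#' the classic equal-variance test), paired when comparing readouts on the
#' same combinations and unpaired when comparing independent well sets (e.g.
#' 2D vs 3D). Stars follow the usual convention: `*`, `**`, `***` at
#' p <= 0.05, 0.01 and 0.001.
#'
#' @param a,b numeric vectors of per-condition means (at least 2 each; paired
#'   mode requires equal lengths in matched order).
#' @param paired logical.
#' @param var_equal logical; classic Student instead of Welch.
#' @return List with `statistic`, `p_value`, `stars`, `mean_difference`
#'   (mean(a) - mean(b)), `paired`.
#' @export
compare_groups <- function(a, b, paired = FALSE, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per group")
  if (paired && length(a) != length(b)) {
    abort("paired mode requires equal-length, matched vectors")
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal,
                      alternative = "two.sided")
  p <- tt$p.value
  stars <- if (is.na(p)) "" else if (p <= 0.001) "***" else
    if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  list(statistic = unname(tt$statistic), p_value = p, stars = stars,
       mean_difference = mean(a) - mean(b), paired = paired)
}

#' Coefficient of variation of replicate measurements
#'
#' Sample (n-1) standard deviation divided by the mean; the screen-level
#' technical-variability metric, computed per condition.
#'
#' @param values numeric vector of at least 2 replicate measurements with
#'   non-zero mean.
#' @return Numeric scalar CV (unitless, >= 0 for positive-mean data).
#' @export
cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("need at least 2 values")
  m <- mean(values)
  if (m == 0) abort("zero mean: CV undefined")
  stats::sd(values) / m
}

#' Per-condition coefficients of variation across technical replicates
#'
#' One CV per condition, where a condition is a unique (cell line, format,
#' treatment, readout, timepoint, biological replicate) combination and the
#' replicates are its technical wells.
#'
#' @param normalized tibble from [normalize_dataset()].
#' @return Tibble with the condition keys, `cv` and `n_tech`. Conditions with
#'   fewer than 2 technical replicates are dropped.
#' @export
condition_cv <- function(normalized) {
  normalized |>
    filter(.data$role == "treatment") |>
    group_by(.data$cell_line, .data$culture_format, .data$drug_a,
             .data$dose_a, .data$drug_b, .data$dose_b, .data$readout,
             .data$timepoint, .data$bio_rep) |>
    summarise(n_tech = n(),
              cv = if (n() >= 2 && mean(.data$value_norm) != 0) {
                cv(.data$value_norm)
              } else NA_real_,
              .groups = "drop") |>
    filter(!is.na(.data$cv))
}

#' Overall CV per biological replicate and readout
#'
#' Unweighted mean of the condition-level CVs within each
#' (biological replicate, readout) stratum.
#'
#' @param cv_table tibble from [condition_cv()] (columns `bio_rep`, `readout`,
#'   `cv`; a `culture_format` column, if present, is kept as a stratum).
#' @return Tibble with `cv_overall` and `n_conditions` per stratum.
#' @export
overall_cv <- function(cv_table) {
  if (nrow(cv_table) == 0) abort("empty CV table")
  strata <- intersect(c("culture_format", "readout", "bio_rep"),
                      names(cv_table))
  cv_table |>
    group_by(across(dplyr::all_of(strata))) |>
    summarise(cv_overall = mean(.data$cv), n_conditions = n(),
              .groups = "drop")
}

#' Replicate correlations: screen reproducibility
#'
#' Intra-screen reproducibility correlates biological replicate 1 against
#' replicate 2 on all shared conditions (per readout and culture format).
#' Inter-screen reproducibility correlates single-agent doses shared between
#' the single-drug screen (wells with an empty second drug slot) and the
#' combination screen's single-agent edges (second drug named, dose zero),
#' per culture format, on technical-replicate means.
#'
#' @param normalized tibble from [normalize_dataset()].
#' @param level `"intra_screen"` or `"inter_screen"`.
#' @return Tibble with the comparison strata, `pearson_r` and `n_points`.
#' @export
replicate_correlation <- function(normalized,
                                  level = c("intra_screen", "inter_screen")) {
  level <- match.arg(level)
  trt <- filter(normalized, .data$role == "treatment")
  if (level == "intra_screen") {
    means <- trt |>
      group_by(.data$culture_format, .data$readout, .data$cell_line,
               .data$drug_a, .data$dose_a, .data$drug_b, .data$dose_b,
               .data$timepoint, .data$bio_rep) |>
      summarise(value_norm = mean(.data$value_norm), .groups = "drop")
    wide <- tidyr::pivot_wider(means, names_from = "bio_rep",
                               values_from = "value_norm",
                               names_prefix = "rep")
    if (!all(c("rep1", "rep2") %in% names(wide))) {
      abort("intra-screen correlation needs biological replicates 1 and 2")
    }
    wide <- filter(wide, !is.na(.data$rep1), !is.na(.data$rep2))
    if (nrow(wide) == 0) abort("no conditions shared between replicates")
    wide |>
      group_by(.data$culture_format, .data$readout) |>
      summarise(pearson_r = pearson_r(.data$rep1, .data$rep2)$r,
                n_points = n(), .groups = "drop") |>
      mutate(level = "intra_screen", .before = 1)
  } else {
    single <- trt |>
      filter(.data$drug_b == "", .data$drug_a != "") |>
      group_by(.data$culture_format, .data$readout, .data$cell_line,
               .data$drug_a, .data$dose_a) |>
      summarise(v_single = mean(.data$value_norm), .groups = "drop")
    edges <- trt |>
      filter(.data$drug_a != "", .data$drug_b != "",
             xor(.data$dose_a > 0, .data$dose_b > 0)) |>
      mutate(drug = ifelse(.data$dose_a > 0, .data$drug_a, .data$drug_b),
             dose = pmax(.data$dose_a, .data$dose_b)) |>
      group_by(.data$culture_format, .data$readout, .data$cell_line,
               .data$drug, .data$dose) |>
      summarise(v_combo = mean(.data$value_norm), .groups = "drop") |>
      rename(drug_a = "drug", dose_a = "dose")
    shared <- dplyr::inner_join(
      single, edges,
      by = c("culture_format", "readout", "cell_line", "drug_a", "dose_a"))
    if (nrow(shared) == 0) abort("no single-agent doses shared between screens")
    shared |>
      group_by(.data$culture_format, .data$readout) |>
      summarise(pearson_r = pearson_r(.data$v_single, .data$v_combo)$r,
                n_points = n(), .groups = "drop") |>
      mutate(level = "inter_screen", .before = 1)
  }
}
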