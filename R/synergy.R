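#' Bliss independence expectation on the effect scale
#'
#' Under Bliss independence two non-interacting drugs with fractional effects
#' `e_a` and `e_b` (effect = 1 - relative viability) combine to
#' `e_a + e_b - e_a * e_b`. Inputs outside [0, 1] are clamped; deviations
#' larger than 0.5 trigger a warning since they indicate a normalization
#' problem rather than assay noise.
#'
#' @param e_a,e_b fractional effects in [0, 1] (vectorized).
#' @return Expected combined effect, in [0, 1].
#' @examples
#' bliss_expected_effect(0.5, 0.5) # 0.75
#' @export
bliss_expected_effect <- function(e_a, e_b) {
  out_by <- pmax(pmax(e_a - 1, -e_a, 0), pmax(e_b - 1, -e_b, 0))
  if (any(out_by > 0.5, na.rm = TRUE)) {
    warn("effect input outside [0, 1] by more than 0.5; check normalization (clamped)")
  }
  e_a <- .clamp(e_a, 0, 1)
  e_b <- .clamp(e_b, 0, 1)
  e_a + e_b - e_a * e_b
}

#' Bliss excess on the viability scale
#'
#' The Bliss expectation for relative viabilities is the product
#' `v_a * v_b` of the (clamped) single-agent viabilities; the excess is
#' `v_obs - v_a * v_b`. Negative excess means the combination kills more than
#' expected from independence — synergy; positive excess is antagonism. This
#' equals the effect-scale expectation minus the observed effect with
#' effect = 1 - viability (exact algebraic identity).
#'
#' @param v_obs observed combination relative viability (>= 0, not clamped).
#' @param v_a,v_b single-agent relative viabilities, clamped to [0, 1] before
#'   the product so that supra-vehicle single-agent noise cannot manufacture
#'   spurious synergy.
#' @return Bliss excess (vectorized); negative = synergy.
#' @examples
#' bliss_excess(0.2, 0.6, 0.5) # -0.10: synergy
#' @export
bliss_excess <- function(v_obs, v_a, v_b) {
  v_obs - .clamp(v_a, 0, 1) * .clamp(v_b, 0, 1)
}

#' Score a dose matrix against the Bliss independence model
#'
#' For each non-zero dose pair (i, j), the single-agent viabilities are taken
#' from the matrix's own dose-zero edges (same plate, same biological
#' replicate), clamped to [0, 1], and the cell's excess is
#' `observed - v_a * v_b`. Missing edge cells make all dependent excess cells
#' missing.
#'
#' @param matrix a [dose_matrix()] with populated single-agent edges.
#' @return An object of class `bliss_grid`: matrices `excess`, `observed`,
#'   `expected` over the non-zero dose grid, plus identity fields.
#' @export
score_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "dose_matrix"))
  r <- matrix$response
  k <- nrow(r) - 1L
  m <- ncol(r) - 1L
  if (k < 1 || m < 1) abort("dose matrix has no non-zero doses")
  v_a <- r[-1, 1]
  v_b <- r[1, -1]
  if (any(stats::na.omit(c(v_a, v_b)) > 1 + 1e-9)) {
    warn("single-agent viability > 1 clamped before Bliss product")
  }
  expected <- outer(.clamp(v_a, 0, 1), .clamp(v_b, 0, 1))
  observed <- r[-1, -1, drop = FALSE]
  structure(
    list(excess = observed - expected, observed = observed,
         expected = expected,
         doses_a = matrix$doses_a[-1], doses_b = matrix$doses_b[-1],
         cell_line = matrix$cell_line,
         culture_format = matrix$culture_format,
         drug_a = matrix$drug_a, drug_b = matrix$drug_b,
         readout = matrix$readout, bio_rep = matrix$bio_rep,
         sd_excess = NULL,
         n_rep = matrix(1L, k, m)),
    class = "bliss_grid"
  )
}

#' @export
print.bliss_grid <- function(x, ...) {
  cat(sprintf("<bliss_grid> %s + %s | %s %s | %s | bio rep %s\n",
              x$drug_a, x$drug_b, x$cell_line, x$culture_format,
              x$readout, paste(x$bio_rep, collapse = ",")))
  m <- round(x$excess, 3)
  dimnames(m) <- list(paste0(x$drug_a, "=", signif(x$doses_a, 3)),
                      paste0(x$drug_b, "=", signif(x$doses_b, 3)))
  print(m)
  invisible(x)
}

#' Average Bliss grids across biological replicates
#'
#' Cellwise mean (and standard deviation, sample n-1) of the excess, observed
#' and expected grids over replicates; cells missing in a replicate are
#' skipped, so a dose pair dropped from one replicate is still scored from the
#' remaining one.
#'
#' @param grids list of `bliss_grid` objects for the same matrix identity.
#' @param tol relative tolerance when checking dose-axis congruence.
#' @return A `bliss_grid` whose `excess`/`observed`/`expected` are cellwise
#'   means, with `sd_excess` and per-cell replicate counts `n_rep`.
#' @export
average_replicates <- function(grids, tol = 1e-9) {
  if (length(grids) < 1) abort("need at least one grid")
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    same <- identical(c(g$drug_a, g$drug_b, g$cell_line, g$culture_format,
                        g$readout),
                      c(g1$drug_a, g1$drug_b, g1$cell_line,
                        g1$culture_format, g1$readout)) &&
      length(g$doses_a) == length(g1$doses_a) &&
      length(g$doses_b) == length(g1$doses_b) &&
      all(abs(g$doses_a - g1$doses_a) <= tol * pmax(1, g1$doses_a)) &&
      all(abs(g$doses_b - g1$doses_b) <= tol * pmax(1, g1$doses_b))
    if (!same) abort("incompatible dose axes or grid identities")
  }
  stack <- function(field) {
    arr <- vapply(grids, `[[`, g1[[field]], field)
    dim(arr) <- c(dim(g1[[field]]), length(grids))
    arr
  }
  exc <- stack("excess")
  g1$excess <- apply(exc, c(1, 2), mean, na.rm = TRUE)
  g1$excess[is.nan(g1$excess)] <- NA_real_
  g1$sd_excess <- apply(exc, c(1, 2), stats::sd, na.rm = TRUE)
  g1$observed <- apply(stack("observed"), c(1, 2), mean, na.rm = TRUE)
  g1$observed[is.nan(g1$observed)] <- NA_real_
  g1$expected <- apply(stack("expected"), c(1, 2), mean, na.rm = TRUE)
  g1$expected[is.nan(g1$expected)] <- NA_real_
  g1$n_rep <- apply(!is.na(exc), c(1, 2), sum)
  g1$bio_rep <- vapply(grids, function(g) g$bio_rep[1], g1$bio_rep[1])
  g1
}

#' Summarise a Bliss grid into a one-row synergy call
#'
#' The matrix-level synergy score is the mean Bliss excess over the non-zero
#' dose cells (missing cells skipped); a combination is called synergistic
#' when that mean is strictly below 0. The joint "synergistically effective"
#' classifier additionally requires strong growth inhibition: a dose pair is
#' synergistically effective when its excess is strictly below 0 AND its
#' observed combination viability is at or below `effectiveness_threshold`
#' (default 0.5, i.e. at most 50% of vehicle).
#'
#' @param grid a `bliss_grid` (single replicate or replicate-averaged).
#' @param effectiveness_threshold viability cut for the effectiveness gate.
#' @return One-row tibble: identity columns, `mean_excess`, `sd_excess`
#'   (across the matrix cells), `mean_viability` (mean observed combination
#'   viability over the non-zero dose cells), `synergistic`, `n_effective`,
#'   and `effective_doses` (list column of dose pairs passing both gates).
#' @export
summarize_synergy <- function(grid, effectiveness_threshold = 0.5) {
  stopifnot(inherits(grid, "bliss_grid"))
  if (all(is.na(grid$excess))) abort("all grid cells missing")
  mean_excess <- mean(grid$excess, na.rm = TRUE)
  eff <- which(!is.na(grid$excess) & grid$excess < 0 &
                 !is.na(grid$observed) &
                 grid$observed <= effectiveness_threshold,
               arr.ind = TRUE)
  eff_doses <- tibble(
    dose_a = grid$doses_a[eff[, 1]],
    dose_b = grid$doses_b[eff[, 2]],
    excess = grid$excess[eff],
    viability = grid$observed[eff]
  )
  tibble(
    cell_line = grid$cell_line, culture_format = grid$culture_format,
    drug_a = grid$drug_a, drug_b = grid$drug_b,
    combination = pair_key(grid$drug_a, grid$drug_b),
    readout = grid$readout,
    mean_excess = mean_excess,
    sd_excess = stats::sd(grid$excess, na.rm = TRUE),
    mean_viability = mean(grid$observed, na.rm = TRUE),
    synergistic = mean_excess < 0,
    n_effective = nrow(eff_doses),
    effective_doses = list(eff_doses)
  )
}

#' Count synergistic combinations per culture format
#'
#' A combination counts once per format when its matrix-mean Bliss excess is
#' below 0 in at least one cell line. Per-(combination, cell line) mean
#' excess values are additionally binned into Bliss-excess intervals for the
#' interval-histogram report.
#'
#' @param summaries tibble of synergy summaries ([summarize_synergy()] rows),
#'   covering every combination x cell line for each format present.
#' @param bin_edges interior bin edges for the Bliss-excess histogram.
#' @return List with `counts` (per format: combinations synergistic in >= 1
#'   cell line, and totals) and `bins` (per format histogram of
#'   per-combination-cell-line mean excess).
#' @export
count_synergies <- function(summaries,
                            bin_edges = c(-0.2, -0.1, -0.05, 0,
                                          0.05, 0.1, 0.2)) {
  need <- c("cell_line", "culture_format", "combination",
            "mean_excess", "synergistic")
  stopifnot(all(need %in% names(summaries)))
  full <- tidyr::expand_grid(
    culture_format = unique(summaries$culture_format),
    combination = unique(summaries$combination),
    cell_line = unique(summaries$cell_line)
  )
  got <- distinct(summaries, .data$culture_format, .data$combination,
                  .data$cell_line)
  miss <- dplyr::anti_join(full, got,
                           by = c("culture_format", "combination", "cell_line"))
  if (nrow(miss) > 0) {
    abort(paste0("incomplete summary set; missing: ",
                 paste(utils::head(paste(miss$culture_format, miss$combination,
                                         miss$cell_line), 5), collapse = "; "),
                 if (nrow(miss) > 5) " ..." else ""))
  }
  counts <- summaries |>
    group_by(.data$culture_format, .data$combination) |>
    summarise(any_synergy = any(.data$synergistic), .groups = "drop") |>
    group_by(.data$culture_format) |>
    summarise(n_synergistic = sum(.data$any_synergy),
              n_combinations = n(), .groups = "drop")
  edges <- c(-Inf, sort(bin_edges), Inf)
  bins <- summaries |>
    mutate(bin = cut(.data$mean_excess, breaks = edges)) |>
    count(.data$culture_format, .data$bin, name = "n")
  list(counts = counts, bins = bins)
}
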