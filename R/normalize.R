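#' Normalize a raw signal to the vehicle control
#'
#' Treatment effects are expressed relative to the mean of the solvent-only
#' (vehicle) wells measured on the same plate, for the same readout and
#' timepoint, so that vehicle = 1 by construction and a value of 0.5 means
#' half the vehicle signal.
#'
#' @param raw numeric raw signal(s) to normalize.
#' @param vehicle_values raw signals of the vehicle wells from the same
#'   plate, readout and timepoint (at least one, positive mean).
#' @return An object of class `normalized_value`: a list with `value`
#'   (numeric, same length as `raw`), `basis = "vehicle"` and `n_vehicle`.
#' @examples
#' normalize_to_vehicle(5000, c(10000, 10000))$value # 0.5
#' @export
normalize_to_vehicle <- function(raw, vehicle_values) {
  if (length(vehicle_values) < 1) abort("empty vehicle set")
  m <- mean(vehicle_values)
  if (!is.finite(m) || m <= 0) {
    abort("non-positive vehicle mean: assay failure signal")
  }
  structure(list(value = raw / m, basis = "vehicle",
                 n_vehicle = length(vehicle_values)),
            class = "normalized_value")
}

#' Normalize a kinetic imaging signal to time zero and vehicle growth
#'
#' For kinetic readouts (confluency, apoptosis imaging) the relevant quantity
#' is fold-growth of treated wells relative to fold-growth of vehicle wells:
#' `(raw_t / raw_0) / (mean(vehicle_t) / mean(vehicle_0))`. A value of 1 means
#' treated wells grew exactly as fast as vehicle; 0.5 means half the vehicle
#' fold-growth.
#'
#' @param raw_t,raw_0 treated-well signal at time t and at 0 h.
#' @param vehicle_t,vehicle_0 matched vehicle-well signals at time t and 0 h.
#' @return An object of class `normalized_value` with
#'   `basis = "vehicle_and_t0"`.
#' @examples
#' # treated static while vehicle doubles
#' normalize_kinetic(100, 100, 200, 100)$value # 0.5
#' @export
normalize_kinetic <- function(raw_t, raw_0, vehicle_t, vehicle_0) {
  if (length(vehicle_t) < 1 || length(vehicle_0) < 1) abort("empty vehicle set")
  if (any(!is.finite(raw_0)) || any(raw_0 <= 0)) abort("zero or negative treated baseline")
  g_veh <- mean(vehicle_t) / mean(vehicle_0)
  if (!is.finite(g_veh) || g_veh <= 0) abort("zero or negative vehicle baseline growth")
  structure(list(value = (raw_t / raw_0) / g_veh, basis = "vehicle_and_t0",
                 n_vehicle = length(vehicle_t)),
            class = "normalized_value")
}

#' Normalize all wells of a screen dataset to their per-plate vehicle controls
#'
#' Vehicle wells are matched per (plate, readout, timepoint); every well's
#' value is divided by the mean vehicle signal of its own plate. Vehicle and
#' positive-control wells are carried through (normalized like any other well)
#' so the mean of the normalized vehicle wells on a plate is exactly 1.
#'
#' @param dataset a [screen_dataset()] or bare record table.
#' @return Tibble of the input records plus `value_norm` (unitless, vehicle
#'   = 1) and `n_vehicle` (number of vehicle wells used) columns.
#' @export
normalize_dataset <- function(dataset) {
  records <- as_screen_records(dataset)
  veh_stats <- records |>
    filter(.data$role == "vehicle") |>
    group_by(.data$plate_id, .data$readout, .data$timepoint) |>
    summarise(.veh_mean = mean(.data$value), n_vehicle = n(),
              .groups = "drop")
  out <- left_join(records, veh_stats,
                   by = c("plate_id", "readout", "timepoint"))
  no_veh <- is.na(out$.veh_mean)
  if (any(no_veh)) {
    abort(paste0("no vehicle wells for plate/readout/timepoint: ",
                 paste(utils::head(unique(paste(
                   out$plate_id[no_veh], out$readout[no_veh],
                   out$timepoint[no_veh])), 3), collapse = "; ")))
  }
  bad <- out$.veh_mean <= 0
  if (any(bad)) {
    abort(paste0("non-positive vehicle mean (assay failure) on plate(s): ",
                 paste(utils::head(unique(out$plate_id[bad]), 3),
                       collapse = ", ")))
  }
  out$value_norm <- out$value / out$.veh_mean
  out$.veh_mean <- NULL
  out
}
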