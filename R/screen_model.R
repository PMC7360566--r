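#' Screen data model: per-well records, datasets, and dose matrices
#'
#' A screen dataset is a validated tidy table of per-well measurements from a
#' 384-well drug screen, one row per (plate, well, readout, timepoint). Wells
#' carry their treatment (one or two drugs with doses in micromolar), the cell
#' line and culture format (planar 2D or spheroid 3D), the readout name, and
#' technical/biological replicate indices. Raw values are non-negative signals
#' (luminescence counts, percent confluent area, spheroid diameter in
#' micrometres, fluorescence counts).
#'
#' @name screen_model
NULL

.well_record_cols <- c(
  plate_id = "character", well = "character", cell_line = "character",
  culture_format = "character", role = "character",
  drug_a = "character", dose_a = "double", drug_b = "character",
  dose_b = "double", readout = "character", timepoint = "double",
  tech_rep = "integer", bio_rep = "integer", value = "double"
)

#' Construct a screen dataset from a table of well records
#'
#' Validates the records (see Details) and wraps them together with optional
#' design metadata (drug panel, dose sets, replicate counts).
#'
#' @details Validation enforces: well coordinates parse to a valid 384-well
#'   position (rows A-P, columns 1-24); `culture_format`, `role` and `readout`
#'   take known values; doses, timepoints and values are non-negative; vehicle
#'   wells carry zero doses and no drug names; treatment wells carry at least
#'   one non-zero dose; and `(plate_id, well, readout, timepoint)` uniquely
#'   identifies a record.
#'
#' @param records data frame with one row per measured well; required columns
#'   are `plate_id`, `well`, `cell_line`, `culture_format`, `role`, `drug_a`,
#'   `dose_a`, `drug_b`, `dose_b`, `readout`, `timepoint`, `tech_rep`,
#'   `bio_rep`, `value`. Empty drug slots are `""`.
#' @param design optional named list of design metadata.
#' @return An object of class `screen_dataset` with elements `records`
#'   (a tibble) and `design`.
#' @export
screen_dataset <- function(records, design = list()) {
  records <- validate_well_records(records)
  structure(list(records = records, design = design),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  r <- x$records
  cat("<screen_dataset> ", nrow(r), " well records\n", sep = "")
  cat("  cell lines: ", paste(sort(unique(r$cell_line)), collapse = ", "),
      "\n", sep = "")
  cat("  formats:    ", paste(sort(unique(r$culture_format)), collapse = ", "),
      " | readouts: ", paste(sort(unique(r$readout)), collapse = ", "),
      "\n", sep = "")
  cat("  plates:     ", length(unique(r$plate_id)),
      " | bio reps: ", paste(sort(unique(r$bio_rep)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# accept either a screen_dataset or a bare record table
as_screen_records <- function(x) {
  if (inherits(x, "screen_dataset")) x$records else as_tibble(x)
}

#' Validate a table of well records
#'
#' @param records data frame of well records (see [screen_dataset()]).
#' @return The records as a tibble with canonical column types, invisibly
#'   usable downstream. Errors describe the offending rows.
#' @export
validate_well_records <- function(records) {
  records <- as_tibble(records)
  missing_cols <- setdiff(names(.well_record_cols), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  records <- mutate(
    records,
    across(c("plate_id", "well", "cell_line", "culture_format", "role",
             "drug_a", "drug_b", "readout"), as.character),
    across(c("dose_a", "dose_b", "timepoint", "value"), as.double),
    across(c("tech_rep", "bio_rep"), as.integer),
    drug_a = ifelse(is.na(.data$drug_a), "", .data$drug_a),
    drug_b = ifelse(is.na(.data$drug_b), "", .data$drug_b)
  )

  bad_row <- function(ok, what) {
    if (!all(ok)) {
      abort(paste0("invalid well record(s): ", what, " at row(s) ",
                   paste(utils::head(which(!ok), 5), collapse = ", "),
                   if (sum(!ok) > 5) " ..." else ""))
    }
  }
  bad_row(.valid_well(records$well), "well coordinate not a valid 384-well position")
  bad_row(records$culture_format %in% .synscreen_formats, "unknown culture_format")
  bad_row(records$role %in% .synscreen_roles, "unknown role")
  bad_row(records$readout %in% .synscreen_readouts, "unknown readout")
  bad_row(is.finite(records$dose_a) & records$dose_a >= 0, "negative or non-finite dose_a")
  bad_row(is.finite(records$dose_b) & records$dose_b >= 0, "negative or non-finite dose_b")
  bad_row(is.finite(records$value) & records$value >= 0, "negative or non-finite value")
  bad_row(is.finite(records$timepoint) & records$timepoint >= 0, "negative timepoint")
  bad_row(!is.na(records$tech_rep) & records$tech_rep >= 1L, "tech_rep < 1")
  bad_row(!is.na(records$bio_rep) & records$bio_rep >= 1L, "bio_rep < 1")

  veh <- records$role == "vehicle"
  bad_row(!veh | (records$dose_a == 0 & records$dose_b == 0),
          "vehicle well with non-zero dose")
  trt <- records$role == "treatment"
  bad_row(!trt | (records$dose_a > 0 | records$dose_b > 0),
          "treatment well with no non-zero dose")

  dup <- duplicated(records[c("plate_id", "well", "readout", "timepoint")])
  bad_row(!dup, "duplicate (plate_id, well, readout, timepoint)")

  records
}

#' Read a screen measurement table from a tidy CSV file
#'
#' One measurement per row, UTF-8, header row naming all well-record fields.
#'
#' @param path path to a CSV file.
#' @return A [screen_dataset()].
#' @export
read_screen_csv <- function(path) {
  col_types <- readr::cols(
    plate_id = readr::col_character(), well = readr::col_character(),
    cell_line = readr::col_character(),
    culture_format = readr::col_character(), role = readr::col_character(),
    drug_a = readr::col_character(), dose_a = readr::col_double(),
    drug_b = readr::col_character(), dose_b = readr::col_double(),
    readout = readr::col_character(), timepoint = readr::col_double(),
    tech_rep = readr::col_integer(), bio_rep = readr::col_integer(),
    value = readr::col_double()
  )
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(names(.well_record_cols), header)
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: missing column(s): ",
                 paste(missing_cols, collapse = ", "), " in ", path))
  }
  records <- readr::read_csv(path, col_types = col_types,
                             na = c("", "NA"), show_col_types = FALSE)
  probs <- readr::problems(records)
  if (nrow(probs) > 0) {
    abort(paste0("unparsable value(s) in ", path, " at line(s) ",
                 paste(utils::head(unique(probs$row), 5) + 1L, collapse = ", ")))
  }
  screen_dataset(records)
}

#' Write a screen dataset to a tidy CSV file
#'
#' @param dataset a [screen_dataset()] or bare record table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(dataset, path) {
  records <- as_screen_records(dataset)
  readr::write_csv(records, path)
  invisible(path)
}

#' Enumerate all unordered drug pairs in a panel
#'
#' A panel of n drugs yields n(n-1)/2 pairwise combinations; the screen design
#' tests each pair once, in a 5 x 5 dose matrix.
#'
#' @param drug_panel character vector of at least two distinct drug names.
#' @return Tibble with columns `drug_a`, `drug_b` (lexicographically ordered
#'   within and across pairs) and `combination` (the canonical pair key).
#' @examples
#' enumerate_pairs(c("5-FU", "OXA", "PD"))
#' @export
enumerate_pairs <- function(drug_panel) {
  if (anyDuplicated(drug_panel)) abort("duplicate drug names in panel")
  if (length(drug_panel) < 2) abort("need at least 2 drugs")
  drugs <- sort(drug_panel)
  idx <- utils::combn(length(drugs), 2)
  tibble(
    drug_a = drugs[idx[1, ]],
    drug_b = drugs[idx[2, ]],
    combination = pair_key(drugs[idx[1, ]], drugs[idx[2, ]])
  )
}

#' Construct a dose matrix object
#'
#' A dose matrix holds the normalized responses of one drug pair in one
#' (cell line, culture format, readout, biological replicate) context on a
#' (vehicle + k doses) x (vehicle + m doses) grid. Cell (1, 1) is the double
#' vehicle; row 1 and column 1 hold the single-agent responses.
#'
#' @param cell_line,culture_format,drug_a,drug_b,readout,bio_rep identity.
#' @param doses_a,doses_b ascending dose vectors starting at 0 (micromolar).
#' @param response numeric matrix `length(doses_a)` x `length(doses_b)` of
#'   normalized responses (vehicle = 1); missing cells are `NA`.
#' @param n_tech integer matrix of contributing technical-replicate counts.
#' @return An object of class `dose_matrix`.
#' @export
dose_matrix <- function(cell_line, culture_format, drug_a, drug_b,
                        doses_a, doses_b, response, n_tech,
                        readout, bio_rep) {
  stopifnot(doses_a[1] == 0, doses_b[1] == 0,
            all(diff(doses_a) > 0), all(diff(doses_b) > 0),
            nrow(response) == length(doses_a),
            ncol(response) == length(doses_b),
            all(dim(n_tech) == dim(response)))
  structure(
    list(cell_line = cell_line, culture_format = culture_format,
         drug_a = drug_a, drug_b = drug_b,
         doses_a = doses_a, doses_b = doses_b,
         response = response, n_tech = n_tech,
         readout = readout, bio_rep = bio_rep),
    class = "dose_matrix"
  )
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("<dose_matrix> %s + %s | %s %s | %s | bio rep %s\n",
              x$drug_a, x$drug_b, x$cell_line, x$culture_format,
              x$readout, x$bio_rep))
  m <- round(x$response, 3)
  dimnames(m) <- list(paste0(x$drug_a, "=", signif(x$doses_a, 3)),
                      paste0(x$drug_b, "=", signif(x$doses_b, 3)))
  print(m)
  invisible(x)
}

#' Assemble normalized well values into dose matrices
#'
#' Groups vehicle-normalized combination-screen wells by (cell line, culture
#' format, drug pair) for one readout and biological replicate, and averages
#' technical replicates into grid cells. Single-agent wells (one zero dose)
#' populate the matrix edges; wells with both doses zero and per-plate vehicle
#' wells populate the double-vehicle cell. Grid cells with no contributing
#' wells are flagged missing (`NA`) with a warning, and the matrix is still
#' returned — mirroring the handling of a dose pair dropped from one
#' biological replicate.
#'
#' @param normalized tibble as returned by [normalize_dataset()]: well records
#'   plus a `value_norm` column. Only rows where both drug names are present
#'   (combination-screen wells) contribute to matrices.
#' @param readout readout name to assemble.
#' @param bio_rep biological replicate index to assemble.
#' @param tol relative tolerance for matching doses to grid positions.
#' @return List of [dose_matrix()] objects, ordered by cell line, format and
#'   combination.
#' @export
assemble_dose_matrices <- function(normalized, readout, bio_rep, tol = 1e-9) {
  stopifnot("value_norm" %in% names(normalized))
  ro <- readout
  br <- bio_rep
  combo <- filter(normalized,
                  .data$readout == ro, .data$bio_rep == br,
                  .data$role == "treatment",
                  .data$drug_a != "", .data$drug_b != "")
  if (nrow(combo) == 0) {
    abort(sprintf("no combination wells for readout '%s', bio_rep %d", ro, br))
  }
  # canonical orientation: drug_a is the lexicographically smaller drug
  swap <- combo$drug_a > combo$drug_b
  combo[swap, c("drug_a", "drug_b", "dose_a", "dose_b")] <-
    combo[swap, c("drug_b", "drug_a", "dose_b", "dose_a")]
  combo$combination <- pair_key(combo$drug_a, combo$drug_b)

  veh <- filter(normalized, .data$readout == ro, .data$bio_rep == br,
                .data$role == "vehicle")

  keys <- distinct(combo, .data$cell_line, .data$culture_format,
                   .data$combination, .data$drug_a, .data$drug_b)
  keys <- arrange(keys, .data$cell_line, .data$culture_format,
                  .data$combination)

  out <- vector("list", nrow(keys))
  missing_cells <- character()
  for (k in seq_len(nrow(keys))) {
    g <- filter(combo,
                .data$cell_line == keys$cell_line[k],
                .data$culture_format == keys$culture_format[k],
                .data$combination == keys$combination[k])
    doses_a <- c(0, sort(unique(g$dose_a[g$dose_a > 0])))
    doses_b <- c(0, sort(unique(g$dose_b[g$dose_b > 0])))
    resp <- matrix(NA_real_, length(doses_a), length(doses_b))
    ntec <- matrix(0L, length(doses_a), length(doses_b))
    ia <- vapply(g$dose_a, .dose_index, integer(1), doses = doses_a, tol = tol)
    ib <- vapply(g$dose_b, .dose_index, integer(1), doses = doses_b, tol = tol)
    for (cell in split(seq_len(nrow(g)), interaction(ia, ib, drop = TRUE))) {
      i <- ia[cell[1]]; j <- ib[cell[1]]
      resp[i, j] <- mean(g$value_norm[cell])
      ntec[i, j] <- length(cell)
    }
    # double-vehicle cell: vehicle wells from the plates this pair was run on
    gveh <- filter(veh, .data$plate_id %in% unique(g$plate_id))
    if (nrow(gveh) > 0) {
      resp[1, 1] <- mean(gveh$value_norm)
      ntec[1, 1] <- nrow(gveh)
    }
    miss <- which(is.na(resp), arr.ind = TRUE)
    if (nrow(miss) > 0) {
      missing_cells <- c(missing_cells, sprintf(
        "%s %s %s [%g + %g]", keys$cell_line[k], keys$culture_format[k],
        keys$combination[k], doses_a[miss[, 1]], doses_b[miss[, 2]]))
    }
    out[[k]] <- dose_matrix(
      cell_line = keys$cell_line[k], culture_format = keys$culture_format[k],
      drug_a = keys$drug_a[k], drug_b = keys$drug_b[k],
      doses_a = doses_a, doses_b = doses_b,
      response = resp, n_tech = ntec, readout = ro, bio_rep = br)
  }
  if (length(missing_cells) > 0) {
    warn(paste0("dose-matrix cell(s) with no data, flagged missing: ",
                paste(utils::head(missing_cells, 5), collapse = "; "),
                if (length(missing_cells) > 5) " ..." else ""))
  }
  out
}
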