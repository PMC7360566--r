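#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select group_by summarise ungroup arrange
#'   across left_join bind_rows distinct n row_number pull rename count
#' @importFrom stats rnorm sd setNames
NULL

# enumerations used throughout the package
.synscreen_roles <- c("treatment", "vehicle", "positive_control")
.synscreen_formats <- c("2D", "3D")
.synscreen_readouts <- c("viability", "confluency", "spheroid_size",
                         "celltox", "nucview")

# valid 384-well coordinates: rows A-P, columns 1-24
.valid_well <- function(well) {
  grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", well)
}

# relative-tolerance dose matching; doses are exact printed values so the
# tolerance only absorbs decimal/binary representation error
.dose_index <- function(dose, doses, tol = 1e-9) {
  hit <- which(abs(dose - doses) <= tol * pmax(1, abs(doses)))
  if (length(hit) == 0) NA_integer_ else hit[[1]]
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sequential 384-well coordinates (row-major) for laying out simulated plates
.well_ids <- function(n) {
  stopifnot(n <= 384)
  all_wells <- paste0(rep(LETTERS[1:16], each = 24), rep(1:24, times = 16))
  all_wells[seq_len(n)]
}

# canonical unordered pair key, e.g. "PD + PI"
pair_key <- function(drug_a, drug_b) {
  lo <- pmin(drug_a, drug_b)
  hi <- pmax(drug_a, drug_b)
  paste(lo, hi, sep = " + ")
}
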