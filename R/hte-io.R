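# Tabular I/O for high-throughput experimentation (HTE) outcome tables.
# One row is one well: ligand, substrate, conditions, conversion and ee.

HTE_COLUMNS <- c("ligand_id", "substrate_id", "solvent", "temperature",
                 "pressure", "time", "conversion", "ee")

#' Validate an HTE outcome table
#'
#' Checks the column contract shared by all HTE readers and generators:
#' `temperature` in Kelvin, `pressure` in bar, `time` in hours,
#' `conversion` in \[0, 1\] and signed `ee` in \[-1, 1\].  Violations are
#' reported with their row index.
#'
#' @param records A data frame of HTE wells.
#' @return The input as a tibble, invisibly validated.
#' @export
validate_hte <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(HTE_COLUMNS, names(records))
  if (length(missing)) {
    stop("HTE table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_conv <- which(!is.finite(records$conversion) |
                      records$conversion < 0 | records$conversion > 1)
  if (length(bad_conv)) {
    stop("conversion outside [0, 1] at row ", bad_conv[[1]], call. = FALSE)
  }
  bad_ee <- which(!is.finite(records$ee) | abs(records$ee) > 1)
  if (length(bad_ee)) {
    stop("|ee| > 1 at row ", bad_ee[[1]], call. = FALSE)
  }
  records
}

#' Read an HTE outcome table from CSV
#'
#' @param path CSV file whose header names all HTE columns
#'   (`ligand_id`, `substrate_id`, `solvent`, `temperature` (K),
#'   `pressure` (bar), `time` (h), `conversion`, `ee`).
#' @return A validated tibble; row order is preserved.
#' @export
read_hte_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  records <- readr::read_csv(
    path,
    col_types = readr::cols(
      ligand_id = readr::col_character(),
      substrate_id = readr::col_character(),
      solvent = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_hte(records)
}

#' Write an HTE outcome table to CSV
#'
#' Numeric columns are written with canonical 10-significant-digit
#' formatting, so write -> read -> write is byte-identical.
#'
#' @param records A validated HTE tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hte_table <- function(records, path) {
  records <- validate_hte(records)[, HTE_COLUMNS]
  for (col in names(records)) {
    if (is.numeric(records[[col]])) {
      records[[col]] <- sprintf("%.10g", records[[col]])
    }
  }
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
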