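# The experimental design of the screening campaign, the modeling-subset
# filter, and the outcome transforms (ee <-> ddG, conversion classes).

GAS_CONSTANT_KJ <- 8.314462618e-3 # kJ mol^-1 K^-1

#' The canonical screening design
#'
#' The 17 condition rows of the 37-plate, 96-well screening campaign:
#' five substrates crossed with solvent, temperature, hydrogen pressure and
#' reaction time, 3552 wells in total.  The five rows marked `selected`
#' (methanol throughout; SM1-SM3 at 25 C / 5 bar / 1 h, SM4 and SM5 at
#' 50 C / 5 bar / 16 h; 192 wells each) form the 960-point modeling subset.
#'
#' @return Tibble with columns `substrate_id`, `solvent`, `temperature_c`,
#'   `pressure_bar`, `time_h`, `n_points`, `selected`.
#' @export
#' @examples
#' sum(canonical_design()$n_points) # 3552
canonical_design <- function() {
  tibble::tribble(
    ~substrate_id, ~solvent, ~temperature_c, ~pressure_bar, ~time_h,
    ~n_points, ~selected,
    "SM1", "DCE",  25,  5,  1, 192, FALSE,
    "SM1", "DCE",  25,  5, 16, 192, FALSE,
    "SM1", "DCE",  25, 30, 16, 192, FALSE,
    "SM1", "MeOH", 25,  5,  1, 192, TRUE,
    "SM1", "MeOH", 25,  5, 16, 576, FALSE,
    "SM1", "MeOH", 25, 30, 16, 192, FALSE,
    "SM2", "DCE",  25,  5,  1, 192, FALSE,
    "SM2", "DCE",  25,  5, 16, 192, FALSE,
    "SM2", "MeOH", 25,  5,  1, 192, TRUE,
    "SM2", "MeOH", 25,  5, 16, 192, FALSE,
    "SM3", "DCE",  25,  5,  1, 192, FALSE,
    "SM3", "DCE",  25,  5, 16, 192, FALSE,
    "SM3", "MeOH", 25,  5,  1, 192, TRUE,
    "SM3", "MeOH", 25,  5, 16, 192, FALSE,
    "SM4", "MeOH", 50,  5, 16, 192, TRUE,
    "SM5", "MeOH", 25,  5, 16,  96, FALSE,
    "SM5", "MeOH", 50,  5, 16, 192, TRUE
  )
}

#' Filter HTE records down to the modeling subset
#'
#' Keeps the records whose substrate and conditions match a `selected` row
#' of [canonical_design()] (record temperatures are Kelvin; design rows are
#' Celsius).  Records matching no design row at all are dropped with a
#' warning; records matching unselected rows are dropped silently.  The
#' filter is idempotent.
#'
#' @param records A validated HTE tibble (see [validate_hte()]).
#' @param design A design table; defaults to [canonical_design()].
#' @return The filtered tibble, row order preserved.
#' @export
select_modeling_subset <- function(records, design = canonical_design()) {
  records <- validate_hte(records)
  if (!nrow(records)) return(records)
  key <- function(substrate, solvent, temp_k, pressure, time) {
    sprintf("%s|%s|%.2f|%.2f|%.2f", substrate, solvent, temp_k, pressure,
            time)
  }
  rec_key <- key(records$substrate_id, records$solvent,
                 records$temperature, records$pressure, records$time)
  design_key <- key(design$substrate_id, design$solvent,
                    design$temperature_c + 273.15, design$pressure_bar,
                    design$time_h)
  unmatched <- !(rec_key %in% design_key)
  if (any(unmatched)) {
    warning(sum(unmatched), " record(s) match no design row and were ",
            "dropped", call. = FALSE)
  }
  records[rec_key %in% design_key[design$selected], ]
}

#' Convert enantiomeric excess to the free-energy difference
#'
#' The Gibbs relation between the enantiomeric excess and the free-energy
#' difference of the two diastereomeric transition states:
#' `ddG = R T ln((1 + ee) / (1 - ee))` in kJ/mol.  Positive ddG favours
#' the (+)-ee enantiomer.
#'
#' @param ee Signed enantiomeric excess, strictly inside (-1, 1).
#' @param temperature Reaction temperature in Kelvin (default 298.15).
#' @return ddG in kJ/mol (vectorised).
#' @export
#' @examples
#' ee_to_ddg(0.90, 298.15) # ~7.30 kJ/mol
ee_to_ddg <- function(ee, temperature = 298.15) {
  if (any(!is.finite(ee) | abs(ee) >= 1)) {
    stop("|ee| must be < 1: the free-energy difference diverges at ",
         "complete enantiopurity", call. = FALSE)
  }
  GAS_CONSTANT_KJ * temperature * log((1 + ee) / (1 - ee))
}

#' Convert a free-energy difference back to enantiomeric excess
#'
#' Exact inverse of [ee_to_ddg()]: `ee = tanh(ddG / (2 R T))`.
#'
#' @param ddg Free-energy difference in kJ/mol.
#' @param temperature Reaction temperature in Kelvin (default 298.15).
#' @return Signed ee in (-1, 1) (vectorised).
#' @export
ddg_to_ee <- function(ddg, temperature = 298.15) {
  tanh(ddg / (2 * GAS_CONSTANT_KJ * temperature))
}

#' Classify conversion into high/low
#'
#' @param conversion Conversion fraction(s) in \[0, 1\].
#' @param threshold Class boundary; conversion at or above it is "high"
#'   (default 0.8).
#' @return Factor with levels `low`, `high`.
#' @export
label_conversion <- function(conversion, threshold = 0.8) {
  factor(ifelse(conversion >= threshold, "high", "low"),
         levels = c("low", "high"))
}
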