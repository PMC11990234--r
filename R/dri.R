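#' Dietary Reference Intakes for adolescents aged 14-18 years
#'
#' The built-in DRI registry used by the FNI: one RDA or AI per nutrient and
#' sex for the 14-18 y life-stage group. Where the reference value is a range
#' across sexes, the lower bound belongs to females and the upper to males,
#' as in the standard DRI tables (choline AI 400/550 mg, potassium AI
#' 2300/3000 mg, magnesium AI 360/410 mg, zinc RDA 9/11 mg, vitamin C RDA
#' 65/75 mg); calcium (1300 mg), folate (400 mcg DFE) and vitamin D (15 mcg)
#' are sex-invariant.
#'
#' @return A tibble with columns `nutrient`, `sex`, `reference_type`,
#'   `value`, `unit`, `life_stage`; 16 rows (8 nutrients x 2 sexes).
#' @examples
#' default_dri_table()
#' @export
default_dri_table <- function() {
  path <- system.file("extdata", "dri_adolescent_14_18.csv",
                      package = "fnimenu", mustWork = TRUE)
  read_dri_table(path)
}

#' Read a DRI reference table from CSV
#'
#' Expected columns: `nutrient`, `sex`, `reference_type`, `value`, `unit`,
#' `life_stage`. The table must contain exactly one row per (nutrient, sex)
#' pair for all eight tracked nutrients and both sexes; scoring fails fast on
#' incomplete tables.
#'
#' @param path Path to a CSV file.
#' @return A validated DRI tibble.
#' @export
read_dri_table <- function(path) {
  dri <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(value = readr::col_double(),
                                                 .default = readr::col_character()))
  validate_dri_table(dri)
}

#' Validate a DRI table
#'
#' @param dri A data frame of DRI entries.
#' @return The table as a tibble, invisibly unchanged, if valid; otherwise an
#'   error describing the first violation.
#' @export
validate_dri_table <- function(dri) {
  dri <- tibble::as_tibble(dri)
  required <- c("nutrient", "sex", "reference_type", "value")
  missing <- setdiff(required, names(dri))
  if (length(missing) > 0) {
    rlang::abort(paste0("DRI table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  keys <- .nutrient_keys()
  want <- tidyr::expand_grid(nutrient = keys, sex = c("female", "male"))
  have <- dplyr::distinct(dri, .data$nutrient, .data$sex)
  gap <- dplyr::anti_join(want, have, by = c("nutrient", "sex"))
  if (nrow(gap) > 0) {
    rlang::abort(paste0("DRI table incomplete: no entry for ",
                        gap$nutrient[1], " (", gap$sex[1], ")."))
  }
  if (nrow(dri) != nrow(dplyr::distinct(dri, .data$nutrient, .data$sex))) {
    rlang::abort("DRI table has duplicate (nutrient, sex) entries.")
  }
  if (any(!is.finite(dri$value)) || any(dri$value <= 0)) {
    rlang::abort("All DRI values must be positive.")
  }
  mixed <- dri |>
    dplyr::filter(.data$nutrient %in% keys) |>
    dplyr::summarise(n_types = dplyr::n_distinct(.data$reference_type),
                     .by = "nutrient") |>
    dplyr::filter(.data$n_types > 1)
  if (nrow(mixed) > 0) {
    rlang::abort(paste0("Reference type differs across sexes for ",
                        mixed$nutrient[1], "."))
  }
  dri
}

#' Look up one DRI value
#'
#' @param dri A validated DRI table.
#' @param nutrient One of the eight tracked nutrient keys.
#' @param sex `"female"` or `"male"`.
#' @return A one-row tibble with `value` and `reference_type`.
#' @examples
#' dri_lookup(default_dri_table(), "calcium", "female") # RDA 1300 mg
#' @export
dri_lookup <- function(dri, nutrient, sex) {
  sex <- match.arg(sex, c("female", "male"))
  row <- dri[dri$nutrient == nutrient & dri$sex == sex, ]
  if (nrow(row) != 1) {
    rlang::abort(paste0("No DRI entry for ", nutrient, " (", sex, ")."))
  }
  dplyr::select(row, "nutrient", "sex", "reference_type", "value")
}

# wide helper: per nutrient, female and male reference values in registry order
.dri_wide <- function(dri) {
  dri <- validate_dri_table(dri)
  dri |>
    dplyr::filter(.data$nutrient %in% .nutrient_keys()) |>
    dplyr::select("nutrient", "sex", "value") |>
    tidyr::pivot_wider(names_from = "sex", values_from = "value") |>
    dplyr::arrange(match(.data$nutrient, .nutrient_keys()))
}
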