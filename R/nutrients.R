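#' The eight tracked micronutrients
#'
#' Registry of the micronutrients scored by the Food Nutrient Index in this
#' package: the shortfall nutrients of adolescent diets (choline, potassium,
#' calcium, folate, magnesium, zinc, vitamin D, vitamin C). The registry fixes
#' the canonical key, display unit, and the column names used in totals tables
#' (`<nutrient>_<unit>`) and menu plans (`<nutrient>_<unit>_per_100g`).
#'
#' @return A tibble with columns `nutrient`, `unit`, `amount_col`,
#'   `density_col`.
#' @examples
#' fni_nutrients()
#' @export
fni_nutrients <- function() {
  tibble::tibble(
    nutrient = c("choline", "potassium", "calcium", "folate",
                 "magnesium", "zinc", "vitamin_d", "vitamin_c"),
    unit = c("mg", "mg", "mg", "mcg DFE", "mg", "mg", "mcg", "mg"),
    amount_col = c("choline_mg", "potassium_mg", "calcium_mg", "folate_mcg",
                   "magnesium_mg", "zinc_mg", "vitamin_d_mcg", "vitamin_c_mg")
  ) |>
    dplyr::mutate(density_col = paste0(.data$amount_col, "_per_100g"))
}

# canonical orderings used throughout; cheap enough to recompute
.nutrient_keys <- function() fni_nutrients()$nutrient
.amount_cols <- function() fni_nutrients()$amount_col
.density_cols <- function() fni_nutrients()$density_col

# density columns carried on menu plans: energy and protein ride along for
# the substitution selector and energy reporting, but are never FNI-scored
.plan_density_cols <- function() {
  c("energy_kcal_per_100g", "protein_g_per_100g", .density_cols())
}

#' Scale per-100 g nutrient densities to a served amount
#'
#' @param density A named numeric vector (or one-row data frame) of per-100 g
#'   nutrient densities.
#' @param grams Served amount in grams; must be a single non-negative number.
#' @return A named numeric vector of nutrient amounts in the density's units.
#' @examples
#' scale_to_grams(c(choline_mg_per_100g = 300), 44) # 132 mg
#' @export
scale_to_grams <- function(density, grams) {
  if (is.data.frame(density)) {
    stopifnot(nrow(density) == 1)
    density <- unlist(density[vapply(density, is.numeric, logical(1))])
  }
  stopifnot(is.numeric(density), is.numeric(grams), length(grams) == 1)
  if (is.na(grams) || grams < 0) {
    rlang::abort("`grams` must be a single non-negative number.")
  }
  out <- density * grams / 100
  names(out) <- sub("_per_100g$", "", names(out))
  out
}
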