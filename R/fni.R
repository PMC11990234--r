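#' FNI component score for one nutrient amount
#'
#' A Food Nutrient Index component is the percent of the reference intake
#' (RDA or AI) supplied by the daily amount, capped at 100. Because the
#' adolescent references are sex-specific, the score is computed per sex --
#' `min(100, 100 * amount / dri)` -- and the two sexes are then averaged.
#' The cap is applied before averaging: a menu that exceeds the female
#' reference but not the male one is credited 100 for females only.
#'
#' @param amount Daily nutrient amount, in the nutrient's unit. Vectorized.
#' @param dri_female,dri_male Positive reference values (RDA or AI) for each
#'   sex.
#' @return Sex-averaged component score(s) in \[0, 100\].
#' @examples
#' component_score(624, 1300, 1300) # 48: the calcium worked example
#' component_score(386.57, 400, 550) # HUSS choline, about 83.5
#' @export
component_score <- function(amount, dri_female, dri_male) {
  if (any(dri_female <= 0) || any(dri_male <= 0)) {
    rlang::abort("DRI values must be positive.")
  }
  if (any(amount < 0)) {
    rlang::abort("Nutrient amounts must be non-negative.")
  }
  (pmin(100, 100 * amount / dri_female) +
     pmin(100, 100 * amount / dri_male)) / 2
}

#' Daily nutrient totals of a menu plan
#'
#' Sums `grams * density / 100` over the foods of each day for every
#' per-100 g density column present (the eight tracked nutrients plus energy
#' and protein when available).
#'
#' @param plan A validated menu-plan tibble.
#' @return A totals tibble: `day` plus amount columns (`choline_mg`, ...,
#'   and `energy_kcal` / `protein_g` when densities are present).
#' @export
plan_daily_totals <- function(plan) {
  plan <- validate_menu_plan(plan)
  dens <- intersect(.plan_density_cols(), names(plan))
  totals <- plan |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(dplyr::across(tidyselect::all_of(dens),
                                   ~sum(.x * .data$grams / 100)),
                     .groups = "drop") |>
    dplyr::arrange(.data$day)
  names(totals) <- sub("_per_100g$", "", names(totals))
  totals
}

# per-sex capped scores for a vector of amounts in registry order
.score_by_sex <- function(amounts, dri_wide) {
  tibble::tibble(
    nutrient = dri_wide$nutrient,
    female = pmin(100, 100 * amounts / dri_wide$female),
    male = pmin(100, 100 * amounts / dri_wide$male)
  )
}

#' Score a totals table with the Food Nutrient Index
#'
#' Two aggregation modes are offered:
#'
#' * `"mean_of_days"` (the index's defining construction): average each
#'   nutrient's daily amounts across days first, then score the means. This
#'   is the mode used for menu-level FNI reporting.
#' * `"per_day"`: score each day separately (equal-weight mean of the eight
#'   sex-averaged components per day) and summarise the daily totals with
#'   their mean and sample SD. Useful for attaching dispersion and paired
#'   tests to the total score; because the component cap is nonlinear, the
#'   per-day mean generally differs from the mean-of-days score.
#'
#' @param totals A totals tibble with a `day` column and the eight amount
#'   columns (`choline_mg`, `potassium_mg`, `calcium_mg`, `folate_mcg`,
#'   `magnesium_mg`, `zinc_mg`, `vitamin_d_mcg`, `vitamin_c_mg`), e.g. from
#'   [plan_daily_totals()] or [exemplary_totals()].
#' @param dri A validated DRI table, default [default_dri_table()].
#' @param mode `"mean_of_days"` or `"per_day"`.
#' @return An object of class `fni_result`: a list with `mode`,
#'   `component_by_sex` (nutrient x sex scores), `component` (sex-averaged
#'   scores), `total` (equal-weight mean of the eight components), and in
#'   per-day mode `daily` (day-level totals) and `sd`.
#' @examples
#' fni_score(exemplary_totals("HUSS", "as_given"))
#' @export
fni_score <- function(totals, dri = default_dri_table(),
                      mode = c("mean_of_days", "per_day")) {
  mode <- match.arg(mode)
  totals <- tibble::as_tibble(totals)
  cols <- .amount_cols()
  missing <- setdiff(cols, names(totals))
  if (length(missing) > 0) {
    rlang::abort(paste0("Totals table is missing nutrient column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(totals) == 0) rlang::abort("Totals table is empty.")
  if (any(unlist(totals[cols]) < 0)) {
    rlang::abort("Nutrient totals must be non-negative.")
  }
  dri_wide <- .dri_wide(dri)

  if (mode == "mean_of_days") {
    means <- vapply(totals[cols], mean, numeric(1))
    by_sex <- .score_by_sex(means, dri_wide)
    daily <- NULL
    sd_total <- NA_real_
    component <- by_sex |>
      dplyr::mutate(score = (.data$female + .data$male) / 2) |>
      dplyr::select("nutrient", "score")
    total <- mean(component$score)
  } else {
    day_scores <- purrr::map(seq_len(nrow(totals)), function(i) {
      amounts <- unlist(totals[i, cols])
      s <- .score_by_sex(amounts, dri_wide)
      s$day <- totals$day[i]
      s
    }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(score = (.data$female + .data$male) / 2)
    daily <- day_scores |>
      dplyr::summarise(score = mean(.data$score), .by = "day")
    by_sex <- day_scores |>
      dplyr::summarise(female = mean(.data$female), male = mean(.data$male),
                       .by = "nutrient")
    component <- day_scores |>
      dplyr::summarise(score = mean(.data$score), .by = "nutrient")
    total <- mean(daily$score)
    sd_total <- stats::sd(daily$score)
  }

  structure(
    list(mode = mode,
         component_by_sex = tidyr::pivot_longer(by_sex, c("female", "male"),
                                                names_to = "sex",
                                                values_to = "score"),
         component = component,
         total = total,
         daily = daily,
         sd = sd_total,
         n_days = nrow(totals)),
    class = "fni_result")
}

#' @export
print.fni_result <- function(x, digits = 1, ...) {
  cat("Food Nutrient Index (", x$mode, ", ", x$n_days, " days)\n", sep = "")
  comp <- x$component
  cat(paste0("  ", format(comp$nutrient, width = 10), " ",
             formatC(round(comp$score, digits), format = "f",
                     digits = digits)),
      sep = "\n")
  cat("Total FNI:", formatC(round(x$total, digits), format = "f",
                            digits = digits))
  if (!is.na(x$sd)) {
    cat(" ±", formatC(round(x$sd, digits), format = "f",
                           digits = digits))
  }
  cat("\n")
  invisible(x)
}
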