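#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FNI result
#'
#' @param x An `fni_result`.
#' @param by_sex Return the per-sex component matrix instead of the
#'   sex-averaged scores.
#' @param ... Unused.
#' @return A tibble of component scores with nutrient units.
#' @export
tidy.fni_result <- function(x, by_sex = FALSE, ...) {
  base <- if (by_sex) x$component_by_sex else x$component
  dplyr::left_join(base, dplyr::select(fni_nutrients(), "nutrient", "unit"),
                   by = "nutrient") |>
    dplyr::relocate("unit", .after = "nutrient")
}

#' One-row summary of an FNI result
#'
#' @param x An `fni_result`.
#' @param ... Unused.
#' @return A tibble with `mode`, `total`, `sd` (per-day mode only),
#'   `n_days`, `n_at_cap`.
#' @export
glance.fni_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, total = x$total, sd = x$sd,
                 n_days = x$n_days,
                 n_at_cap = sum(x$component$score >= 100))
}

#' Tidy a price result
#'
#' @param x A `price_result`.
#' @param ... Unused.
#' @return The daily price tibble.
#' @export
tidy.price_result <- function(x, ...) x$daily

#' One-row summary of a price result
#'
#' @param x A `price_result`.
#' @param ... Unused.
#' @return A tibble with `mean_usd`, `sd_usd`, `n_days`, `n_unpriced`.
#' @export
glance.price_result <- function(x, ...) {
  tibble::tibble(mean_usd = x$mean, sd_usd = x$sd, n_days = nrow(x$daily),
                 n_unpriced = nrow(x$missing))
}

#' Tidy a substitution result
#'
#' @param x A `menu_substitution`.
#' @param ... Unused.
#' @return The per-day substitution records (target, rationale, deltas).
#' @export
tidy.menu_substitution <- function(x, ...) x$records

#' One-row summary of a substitution result
#'
#' @param x A `menu_substitution`.
#' @param ... Unused.
#' @return A tibble with day counts by outcome and the summed choline and
#'   vitamin D changes.
#' @export
glance.menu_substitution <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    n_days = nrow(r),
    n_substituted = sum(!is.na(r$target_food_id)),
    n_no_candidate = sum(r$rationale == "no_candidate"),
    n_skipped = sum(r$rationale == "skipped"),
    total_delta_choline_mg = sum(r$delta_choline_mg),
    total_delta_vitamin_d_mcg = sum(r$delta_vitamin_d_mcg))
}
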