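#' Read a menu plan from CSV
#'
#' A menu plan is a tidy table with one row per (day, food). Required
#' columns: `menu`, `day`, `food_id`, `name`, `grams`, `group`
#' (`"protein"`/`"other"`), `protein_subgroup` (`meat_poultry`, `seafood`,
#' `eggs`, `legumes_peas_lentils`, `nuts_seeds_soy`, or `none`),
#' `mixed_dish` (logical), plus per-100 g density columns
#' `<nutrient>_<unit>_per_100g` for the eight tracked nutrients and,
#' optionally, `energy_kcal_per_100g`, `protein_g_per_100g` and
#' `price_per_100g`. Unknown `*_per_100g` columns are dropped with a warning.
#'
#' @param path Path to a CSV file.
#' @return A validated menu-plan tibble.
#' @seealso [write_menu_plan()], [validate_menu_plan()]
#' @export
read_menu_plan <- function(path) {
  plan <- readr::read_csv(path, show_col_types = FALSE)
  if ("day" %in% names(plan)) plan$day <- as.integer(plan$day)
  if ("price_per_100g" %in% names(plan)) {
    plan$price_per_100g <- as.double(plan$price_per_100g)
  }
  known <- c("menu", "day", "food_id", "name", "grams", "group",
             "protein_subgroup", "mixed_dish", "price_per_100g",
             .plan_density_cols())
  extra <- setdiff(grep("_per_100g$", names(plan), value = TRUE), known)
  if (length(extra) > 0) {
    rlang::warn(paste0("Ignoring unknown nutrient column(s): ",
                       paste(extra, collapse = ", ")))
    plan <- dplyr::select(plan, -tidyselect::all_of(extra))
  }
  validate_menu_plan(plan)
}

#' Write a menu plan to CSV
#'
#' @param plan A menu-plan tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_menu_plan <- function(plan, path) {
  validate_menu_plan(plan)
  readr::write_csv(plan, path)
  invisible(path)
}

#' Validate a menu plan
#'
#' Checks the structural invariants the downstream stages rely on: required
#' columns present and numeric where needed, positive grams, day indices
#' consecutive from 1, `food_id` unique within each day, and
#' `protein_subgroup != "none"` exactly for protein-group foods.
#'
#' @param plan A data frame in the menu-plan layout.
#' @return The plan as a tibble if valid; otherwise an error.
#' @export
validate_menu_plan <- function(plan) {
  plan <- tibble::as_tibble(plan)
  required <- c("menu", "day", "food_id", "name", "grams", "group",
                "protein_subgroup", "mixed_dish", .density_cols())
  missing <- setdiff(required, names(plan))
  if (length(missing) > 0) {
    rlang::abort(paste0("Menu plan is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!is.numeric(plan$grams) || any(is.na(plan$grams))) {
    bad <- which(is.na(suppressWarnings(as.numeric(plan$grams))))[1]
    rlang::abort(paste0("Non-numeric grams at day ", plan$day[bad],
                        ", food ", plan$food_id[bad], "."))
  }
  if (any(plan$grams <= 0)) {
    bad <- which(plan$grams <= 0)[1]
    rlang::abort(paste0("grams must be > 0 (day ", plan$day[bad],
                        ", food ", plan$food_id[bad], ")."))
  }
  days <- sort(unique(plan$day))
  if (length(days) == 0 || !identical(as.integer(days),
                                      seq_len(length(days)))) {
    rlang::abort("Day indices must be consecutive integers starting at 1.")
  }
  dup <- plan |>
    dplyr::count(.data$day, .data$food_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(paste0("Duplicate food_id '", dup$food_id[1],
                        "' within day ", dup$day[1], "."))
  }
  bad_sub <- plan$group == "protein" & plan$protein_subgroup == "none" |
    plan$group != "protein" & plan$protein_subgroup != "none"
  if (any(bad_sub)) {
    i <- which(bad_sub)[1]
    rlang::abort(paste0("protein_subgroup must be 'none' iff group is not ",
                        "'protein' (day ", plan$day[i], ", food ",
                        plan$food_id[i], ")."))
  }
  dens <- intersect(.plan_density_cols(), names(plan))
  neg <- plan |>
    dplyr::summarise(dplyr::across(tidyselect::all_of(dens), ~any(.x < 0)))
  if (any(unlist(neg), na.rm = TRUE)) {
    rlang::abort("Per-100 g densities must be non-negative.")
  }
  plan
}

#' Read an as-consumed price table
#'
#' @param path CSV with columns `food_id`, `price_usd_per_100g`.
#' @return A tibble mapping `food_id` to USD per 100 g.
#' @export
read_price_table <- function(path) {
  prices <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = "cd")
  stopifnot(all(c("food_id", "price_usd_per_100g") %in% names(prices)))
  if (any(prices$price_usd_per_100g < 0, na.rm = TRUE)) {
    rlang::abort("Prices must be non-negative.")
  }
  prices
}

#' The boiled-egg profile used for substitution
#'
#' One medium boiled egg: 44 g as served, with per-100 g nutrient densities
#' and an as-consumed price of 0.35 USD/100 g. The densities are standard
#' food-composition reference values for a boiled egg; they are packaged as a
#' convenience default and can be replaced by any one-row profile in the same
#' layout (see `inst/extdata/egg_boiled_reference.csv`).
#'
#' @return A one-row tibble in the menu-plan food layout (`food_id`, `name`,
#'   `grams`, `group = "protein"`, `protein_subgroup = "eggs"`, densities).
#' @examples
#' default_egg_profile()$grams # 44
#' @export
default_egg_profile <- function() {
  path <- system.file("extdata", "egg_boiled_reference.csv",
                      package = "fnimenu", mustWork = TRUE)
  read_egg_profile(path)
}

#' Read an egg (or other swap-in food) profile
#'
#' @param path CSV in key-value layout (`field`, `value`) with `label`,
#'   `food_id`, `grams`, optional `price_usd_per_100g`, and `*_per_100g`
#'   densities.
#' @return A one-row tibble in the menu-plan food layout.
#' @export
read_egg_profile <- function(path) {
  kv <- readr::read_csv(path, show_col_types = FALSE, col_types = "cc")
  get <- function(field) kv$value[match(field, kv$field)]
  dens <- .plan_density_cols()
  vals <- suppressWarnings(as.numeric(vapply(dens, get, character(1))))
  vals[is.na(vals)] <- 0
  profile <- tibble::tibble(
    food_id = get("food_id"),
    name = get("label"),
    grams = as.numeric(get("grams")),
    group = "protein",
    protein_subgroup = "eggs",
    mixed_dish = FALSE,
    price_per_100g = suppressWarnings(as.numeric(get("price_usd_per_100g")))
  )
  profile[dens] <- as.list(vals)
  if (is.na(profile$grams) || profile$grams <= 0) {
    rlang::abort("Egg profile grams must be > 0.")
  }
  profile
}

.fixture_path <- function(file) {
  system.file("extdata", file, package = "fnimenu", mustWork = TRUE)
}

.check_menu <- function(menu) {
  match.arg(menu, c("HUSS", "DASH", "Harvard", "HVEG"))
}

.check_condition <- function(condition) {
  match.arg(condition, c("as_given", "egg_substitution"))
}

#' Packaged daily nutrient totals for the four exemplary menus
#'
#' Transcribed daily totals of the eight tracked nutrients for the four
#' seven-day exemplary menus (HUSS, DASH, Harvard, HVEG), each both as given
#' and after the daily one-egg substitution. Values are stored exactly as
#' printed (one decimal place).
#'
#' @param menu `"HUSS"`, `"DASH"`, `"Harvard"` or `"HVEG"`; `NULL` returns
#'   all menus.
#' @param condition `"as_given"` or `"egg_substitution"`; `NULL` returns both.
#' @return A totals tibble: `menu`, `condition`, `day`, and the eight
#'   `<nutrient>_<unit>` amount columns.
#' @examples
#' exemplary_totals("HUSS", "as_given")
#' @export
exemplary_totals <- function(menu = NULL, condition = NULL) {
  totals <- readr::read_csv(.fixture_path("exemplary_totals.csv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(
                              menu = "c", condition = "c", day = "i",
                              .default = "d"))
  if (!is.null(menu)) totals <- totals[totals$menu == .check_menu(menu), ]
  if (!is.null(condition)) {
    totals <- totals[totals$condition == .check_condition(condition), ]
  }
  totals
}

#' Published daily-mean nutrient rows for the exemplary menus
#'
#' The printed "Daily mean" summary rows accompanying [exemplary_totals()],
#' kept separate so recomputed means can be checked against them.
#'
#' @inheritParams exemplary_totals
#' @return A tibble with `menu`, `condition` and the eight amount columns.
#' @export
exemplary_daily_means <- function(menu = NULL, condition = NULL) {
  means <- readr::read_csv(.fixture_path("exemplary_daily_means.csv"),
                           show_col_types = FALSE,
                           col_types = readr::cols(menu = "c", condition = "c",
                                                   .default = "d"))
  if (!is.null(menu)) means <- means[means$menu == .check_menu(menu), ]
  if (!is.null(condition)) {
    means <- means[means$condition == .check_condition(condition), ]
  }
  means
}

#' Packaged daily menu prices for the four exemplary menus
#'
#' Transcribed total price per day (USD) for each exemplary menu and
#' condition, seven days each.
#'
#' @inheritParams exemplary_totals
#' @return A tibble with `menu`, `condition`, `day`, `price_usd`.
#' @examples
#' exemplary_prices("HUSS", "as_given")$price_usd
#' @export
exemplary_prices <- function(menu = NULL, condition = NULL) {
  prices <- readr::read_csv(.fixture_path("exemplary_prices.csv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(
                              menu = "c", condition = "c", day = "i",
                              price_usd = "d"))
  if (!is.null(menu)) prices <- prices[prices$menu == .check_menu(menu), ]
  if (!is.null(condition)) {
    prices <- prices[prices$condition == .check_condition(condition), ]
  }
  prices
}

#' Published FNI component and total scores for the exemplary menus
#'
#' The printed FNI component scores (per nutrient) and equal-weight totals
#' for all menu-condition pairs, used by [reproduce_menus()] as the
#' comparison surface.
#'
#' @return A tibble with `menu`, `condition`, one column per nutrient, and
#'   `total`.
#' @export
published_fni_scores <- function() {
  readr::read_csv(.fixture_path("fni_published.csv"), show_col_types = FALSE,
                  col_types = readr::cols(menu = "c", condition = "c",
                                          .default = "d"))
}

#' Published mean (SD) daily prices for the exemplary menus
#'
#' @return A tibble with `menu`, `condition`, `mean_usd`, `sd_usd`.
#' @export
published_price_summary <- function() {
  readr::read_csv(.fixture_path("price_summary_published.csv"),
                  show_col_types = FALSE,
                  col_types = readr::cols(menu = "c", condition = "c",
                                          .default = "d"))
}
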