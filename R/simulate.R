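#' Default log-normal density parameters for the synthetic generator
#'
#' Per food group and nutrient, the median and log-scale sigma of the
#' log-normal from which per-100 g densities are drawn. Medians are
#' order-of-magnitude plausible for each group (e.g. seafood rich in vitamin
#' D, legumes in folate, produce in vitamin C); they are generator
#' configuration, not claims about specific foods. Log-normals keep every
#' density positive with realistic right skew.
#'
#' @return A tibble with `group`, `density_col`, `median`, `sigma`.
#' @export
default_density_params <- function() {
  groups <- c("protein_meat", "protein_seafood", "protein_legume",
              "grain", "vegetable", "fruit", "dairy")
  medians <- list(
    energy_kcal_per_100g    = c(200, 150, 120, 250, 40, 60, 70),
    protein_g_per_100g      = c(26, 22, 8, 8, 2, 0.8, 3.5),
    choline_mg_per_100g     = c(80, 70, 30, 15, 15, 7, 15),
    potassium_mg_per_100g   = c(300, 350, 300, 120, 250, 180, 150),
    calcium_mg_per_100g     = c(15, 20, 50, 30, 50, 15, 120),
    folate_mcg_per_100g     = c(8, 12, 100, 50, 60, 20, 10),
    magnesium_mg_per_100g   = c(25, 30, 50, 40, 20, 10, 11),
    zinc_mg_per_100g        = c(4, 1.5, 1.2, 1.5, 0.4, 0.1, 0.4),
    vitamin_d_mcg_per_100g  = c(0.2, 5, 0.02, 0.02, 0.02, 0.02, 1),
    vitamin_c_mg_per_100g   = c(0.5, 1, 2, 0.2, 30, 40, 1))
  purrr::imap(medians, function(m, col) {
    tibble::tibble(group = groups, density_col = col, median = m,
                   sigma = ifelse(col %in% c("energy_kcal_per_100g",
                                             "protein_g_per_100g"),
                                  0.3, 0.4))
  }) |>
    dplyr::bind_rows()
}

#' Configuration for the synthetic menu generator
#'
#' Defaults emulate the structure the analysis assumes: seven-day plans at
#' 2000 kcal/day with several protein-group items of at least 44 g per day,
#' seafood on some days, a share of mixed dishes, and a price table with
#' occasional missing entries.
#'
#' @param days Number of menu days (default 7).
#' @param foods_per_day Integer range `c(min, max)` of foods per day
#'   (default 6--12).
#' @param kcal_target Daily energy target in kcal (default 2000); generated
#'   portion grams are rescaled so each day lands within +/-15% of it.
#' @param protein_items_per_day Non-egg protein foods per day (default 2).
#' @param seafood_days Days (from day 1) whose protein items include one
#'   seafood food (default 2).
#' @param mixed_dish_fraction Probability a protein item is a mixed dish
#'   (default 0.25).
#' @param density_params Log-normal density parameters, see
#'   [default_density_params()].
#' @param price_median,price_sigma Log-normal parameters for USD/100 g
#'   prices (defaults 0.45 and 0.6).
#' @param missing_price_fraction Fraction of foods left out of the generated
#'   price table (default 0.1).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(days = 7, foods_per_day = c(6, 12),
                       kcal_target = 2000, protein_items_per_day = 2,
                       seafood_days = 2, mixed_dish_fraction = 0.25,
                       density_params = default_density_params(),
                       price_median = 0.45, price_sigma = 0.6,
                       missing_price_fraction = 0.1, seed = 1) {
  if (length(foods_per_day) == 1) foods_per_day <- rep(foods_per_day, 2)
  stopifnot(days >= 1, kcal_target > 0, protein_items_per_day >= 1,
            seafood_days >= 0, seafood_days <= days,
            mixed_dish_fraction >= 0, mixed_dish_fraction <= 1,
            missing_price_fraction >= 0, missing_price_fraction <= 1,
            price_median > 0, all(density_params$median > 0))
  if (foods_per_day[1] < protein_items_per_day + 1) {
    rlang::abort("foods_per_day must exceed protein_items_per_day.")
  }
  structure(list(days = days, foods_per_day = foods_per_day,
                 kcal_target = kcal_target,
                 protein_items_per_day = protein_items_per_day,
                 seafood_days = seafood_days,
                 mixed_dish_fraction = mixed_dish_fraction,
                 density_params = density_params,
                 price_median = price_median, price_sigma = price_sigma,
                 missing_price_fraction = missing_price_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# name pools: small on purpose, so the variety rule gets exercised
.name_pool <- list(
  protein_meat = paste("meat item", 1:5),
  protein_seafood = paste("seafood item", 1:3),
  protein_legume = paste("legume item", 1:4),
  grain = paste("grain item", 1:6),
  vegetable = paste("vegetable item", 1:8),
  fruit = paste("fruit item", 1:6),
  dairy = paste("dairy item", 1:4))

.draw_density <- function(group, params) {
  p <- params[params$group == group, ]
  vals <- stats::rlnorm(nrow(p), meanlog = log(p$median), sdlog = p$sigma)
  stats::setNames(as.list(vals), p$density_col)
}

#' Generate a synthetic menu plan
#'
#' Deterministic given `config$seed` (a single pseudo-random stream is
#' consumed day by day, food by food: group assignment, name, densities,
#' then grams). Every day carries `protein_items_per_day` non-egg protein
#' foods of at least 44 g; the first `seafood_days` days include one seafood
#' item; per-day energy is brought within +/-15% of `kcal_target` by uniform
#' rescaling of portion grams (protein portions are then floored at 45 g to
#' preserve substitution eligibility).
#'
#' @param config A [sim_config()].
#' @return A validated menu-plan tibble with a `kcal_target` attribute.
#' @examples
#' plan <- generate_plan(sim_config(seed = 42))
#' dplyr::count(plan, day)
#' @export
generate_plan <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  other_groups <- c("grain", "vegetable", "fruit", "dairy")
  plan <- withr::with_seed(config$seed, {
    purrr::map(seq_len(config$days), function(d) {
      n_foods <- sample(seq(config$foods_per_day[1],
                            config$foods_per_day[2]), 1)
      n_protein <- config$protein_items_per_day
      protein_groups <- if (d <= config$seafood_days) {
        c("protein_seafood",
          sample(c("protein_meat", "protein_legume"), n_protein - 1,
                 replace = TRUE))
      } else {
        sample(c("protein_meat", "protein_legume"), n_protein,
               replace = TRUE)
      }
      groups <- c(protein_groups,
                  sample(other_groups, n_foods - n_protein, replace = TRUE))
      rows <- purrr::imap(groups, function(g, i) {
        is_protein <- g %in% c("protein_meat", "protein_seafood",
                               "protein_legume")
        name <- sample(.name_pool[[g]], 1)
        dens <- .draw_density(g, config$density_params)
        grams <- if (is_protein) stats::runif(1, 80, 200) else
          stats::runif(1, 30, 350)
        mixed <- is_protein && stats::runif(1) < config$mixed_dish_fraction
        tibble::tibble(
          day = d,
          food_id = sprintf("d%02d_f%02d", d, i),
          name = name,
          grams = grams,
          group = if (is_protein) "protein" else "other",
          protein_subgroup = if (!is_protein) "none" else
            switch(g, protein_meat = "meat_poultry",
                   protein_seafood = "seafood",
                   protein_legume = "legumes_peas_lentils"),
          mixed_dish = mixed,
          !!!dens)
      })
      day_tbl <- dplyr::bind_rows(rows)
      energy <- sum(day_tbl$grams * day_tbl$energy_kcal_per_100g / 100)
      day_tbl$grams <- day_tbl$grams * config$kcal_target / energy
      protein_rows <- day_tbl$group == "protein"
      day_tbl$grams[protein_rows] <- pmax(day_tbl$grams[protein_rows], 45)
      day_tbl
    }) |>
      dplyr::bind_rows()
  })
  plan <- dplyr::mutate(plan,
                        menu = sprintf("synthetic_seed%d", config$seed),
                        price_per_100g = NA_real_, .before = 1)
  plan <- validate_menu_plan(plan)
  attr(plan, "kcal_target") <- config$kcal_target
  plan
}

#' Generate a price table for a plan
#'
#' Log-normal USD/100 g prices for all but a deterministic
#' `missing_price_fraction` of the plan's foods (count rounded down), drawn
#' on a stream derived from `config$seed` so plan generation and pricing do
#' not perturb each other.
#'
#' @param plan A menu-plan tibble.
#' @param config A [sim_config()].
#' @return A price tibble (`food_id`, `price_usd_per_100g`).
#' @export
generate_price_table <- function(plan, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- unique(plan$food_id)
  n_missing <- floor(config$missing_price_fraction * length(ids))
  withr::with_seed(config$seed + 1000003L, {
    missing_ids <- sample(ids, n_missing)
    priced <- setdiff(ids, missing_ids)
    tibble::tibble(
      food_id = priced,
      price_usd_per_100g = stats::rlnorm(length(priced),
                                         meanlog = log(config$price_median),
                                         sdlog = config$price_sigma))
  })
}

#' Generate a plan whose mean daily totals sit at a known DRI multiple
#'
#' Rescales the densities of a generated plan so that each tracked
#' nutrient's across-day mean daily total equals
#' `level * mean(dri_female, dri_male)`. With sex-equal DRIs this pins every
#' FNI component to a closed-form value (`100 * min(1, level)`), which makes
#' the scoring pipeline checkable end to end.
#'
#' @param dri A validated DRI table.
#' @param level Positive multiplier of the sex-averaged reference value.
#' @param config A [sim_config()].
#' @return A menu-plan tibble.
#' @export
generate_calibrated_plan <- function(dri, level, config) {
  stopifnot(level > 0)
  plan <- generate_plan(config)
  dri_wide <- .dri_wide(dri)
  totals <- plan_daily_totals(plan)
  reg <- fni_nutrients()
  for (i in seq_len(nrow(reg))) {
    cur <- mean(totals[[reg$amount_col[i]]])
    target <- level * mean(c(dri_wide$female[i], dri_wide$male[i]))
    plan[[reg$density_col[i]]] <- plan[[reg$density_col[i]]] * target / cur
  }
  attr(plan, "kcal_target") <- config$kcal_target
  plan
}
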