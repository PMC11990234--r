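#' Identify protein-source candidates for substitution on one day
#'
#' Candidates are foods in the protein group (meats/poultry, seafood,
#' legumes, nuts/seeds/soy) other than eggs, served in at least `min_grams`
#' so a gram-for-gram swap of one egg is always possible. Candidates are
#' returned in descending order of absolute protein content in the served
#' portion (`grams * protein_g_per_100g / 100`), ties broken by menu order.
#'
#' @param day_foods Rows of a menu plan for a single day.
#' @param min_grams Minimum replaceable portion, default 44 g (one medium
#'   egg).
#' @return The candidate rows with an added `protein_g` column, ordered by
#'   decreasing protein content. Empty tibble if no food qualifies.
#' @export
identify_protein_candidates <- function(day_foods, min_grams = 44) {
  day_foods <- tibble::as_tibble(day_foods)
  stopifnot(length(unique(day_foods$day)) <= 1)
  pd <- if ("protein_g_per_100g" %in% names(day_foods)) {
    dplyr::coalesce(day_foods$protein_g_per_100g, 0)
  } else {
    rep(0, nrow(day_foods))
  }
  day_foods |>
    dplyr::mutate(protein_g = .data$grams * pd / 100,
                  .menu_order = dplyr::row_number()) |>
    dplyr::filter(.data$group == "protein",
                  .data$protein_subgroup != "eggs",
                  .data$grams >= min_grams) |>
    dplyr::arrange(dplyr::desc(.data$protein_g), .data$.menu_order) |>
    dplyr::select(-".menu_order")
}

#' Select one substitution target per day
#'
#' Walks the plan day by day and picks the protein-source food with the
#' highest protein content, subject to two menu-design rules:
#'
#' * **Seafood retention** -- a seafood candidate is passed over if removing
#'   `grams_replaced` of it would drop the plan's weekly seafood total below
#'   the dietary-guidance target (default 226.8 g, i.e. eight ounce-
#'   equivalents per 2000 kcal week, scaled linearly by
#'   `kcal_target / 2000`).
#' * **Variety** -- a candidate whose (subgroup, name) was already selected
#'   on an earlier day is deprioritized below not-yet-used alternatives; it
#'   can still be chosen when nothing else is eligible.
#'
#' Days listed in `skip_days`, and days with no eligible candidate, pass
#' through unsubstituted (`rationale` `"skipped"` / `"no_candidate"`).
#'
#' @param plan A validated menu-plan tibble.
#' @param grams_replaced Grams replaced by the egg, default 44.
#' @param min_grams Candidate eligibility threshold, default `grams_replaced`.
#' @param seafood_weekly_target Weekly seafood grams to retain per 2000 kcal,
#'   default 226.8.
#' @param kcal_target Energy level of the plan used to scale the seafood
#'   target. Defaults to the plan's `kcal_target` attribute, or 2000.
#' @param skip_days Integer days to leave untouched.
#' @return A tibble with one row per day: `day`, `target_food_id`,
#'   `target_name`, `grams_replaced`, `rationale`.
#' @export
select_targets <- function(plan, grams_replaced = 44, min_grams = grams_replaced,
                           seafood_weekly_target = 226.8, kcal_target = NULL,
                           skip_days = integer(0)) {
  plan <- validate_menu_plan(plan)
  if (is.null(kcal_target)) {
    kcal_target <- attr(plan, "kcal_target") %||% 2000
  }
  seafood_target <- seafood_weekly_target * kcal_target / 2000
  seafood_total <- sum(plan$grams[plan$protein_subgroup == "seafood"])
  seafood_removed <- 0
  used <- character(0) # "subgroup||name" keys already substituted
  days <- sort(unique(plan$day))

  records <- purrr::map(days, function(d) {
    rec <- tibble::tibble(day = d, target_food_id = NA_character_,
                          target_name = NA_character_,
                          grams_replaced = 0, rationale = NA_character_)
    if (d %in% skip_days) {
      rec$rationale <- "skipped"
      return(rec)
    }
    cands <- identify_protein_candidates(plan[plan$day == d, ], min_grams)
    if (nrow(cands) == 0) {
      rec$rationale <- "no_candidate"
      return(rec)
    }
    cands <- cands |>
      dplyr::mutate(
        .base_rank = dplyr::row_number(), # already protein-descending
        .is_seafood = .data$protein_subgroup == "seafood",
        .eligible = !.data$.is_seafood |
          (seafood_total - seafood_removed - grams_replaced) >= seafood_target,
        .penalty = as.integer(paste(.data$protein_subgroup, .data$name,
                                    sep = "||") %in% used))
    eligible <- dplyr::filter(cands, .data$.eligible)
    if (nrow(eligible) == 0) {
      rec$rationale <- "no_candidate"
      return(rec)
    }
    chosen <- eligible |>
      dplyr::arrange(.data$.penalty, .data$.base_rank) |>
      dplyr::slice(1)
    best_base <- eligible$food_id[which.min(eligible$.base_rank)]
    seafood_skipped <- any(!cands$.eligible &
                             cands$.base_rank < chosen$.base_rank)
    rationale <- if (chosen$food_id != best_base) {
      "variety_rule_applied"
    } else if (seafood_skipped) {
      "seafood_retained"
    } else {
      "highest_protein"
    }
    used <<- c(used, paste(chosen$protein_subgroup, chosen$name, sep = "||"))
    if (chosen$.is_seafood) {
      seafood_removed <<- seafood_removed + grams_replaced
    }
    rec$target_food_id <- chosen$food_id
    rec$target_name <- chosen$name
    rec$grams_replaced <- grams_replaced
    rec$rationale <- rationale
    rec
  })
  dplyr::bind_rows(records)
}

#' Apply a single egg substitution to one day's foods
#'
#' Pure function: reduces the target food by `grams_replaced`, appends a
#' `grams_replaced` gram egg item (or increments an existing item with the
#' egg's `food_id`), and returns the day's nutrient change. Total grams of
#' the day are unchanged; the nutrient delta is
#' `grams_replaced / 100 * (egg density - target density)` componentwise.
#'
#' @param day_foods Rows of a menu plan for a single day.
#' @param target_food_id The `food_id` to partially replace.
#' @param egg A one-row egg profile, see [default_egg_profile()].
#' @param grams_replaced Grams swapped, default the egg's `grams` (44).
#' @return A list with `foods` (the modified day) and `delta` (named vector
#'   of nutrient changes, names without the `_per_100g` suffix).
#' @export
apply_substitution <- function(day_foods, target_food_id, egg,
                               grams_replaced = egg$grams) {
  day_foods <- tibble::as_tibble(day_foods)
  idx <- which(day_foods$food_id == target_food_id)
  if (length(idx) != 1) {
    rlang::abort(paste0("Target food '", target_food_id,
                        "' not found in day."))
  }
  if (day_foods$grams[idx] < grams_replaced) {
    rlang::abort(paste0("Target food '", target_food_id, "' has only ",
                        day_foods$grams[idx], " g; cannot replace ",
                        grams_replaced, " g."))
  }
  dens <- intersect(.plan_density_cols(), names(day_foods))
  egg_dens <- vapply(dens, function(col) {
    if (col %in% names(egg)) egg[[col]][1] else 0
  }, numeric(1))
  target_dens <- unlist(day_foods[idx, dens])
  delta <- grams_replaced / 100 * (egg_dens - target_dens)
  names(delta) <- sub("_per_100g$", "", dens)

  out <- day_foods
  out$grams[idx] <- out$grams[idx] - grams_replaced
  if (out$grams[idx] == 0) out <- out[-idx, ]
  egg_idx <- which(out$food_id == egg$food_id[1])
  if (length(egg_idx) == 1) {
    out$grams[egg_idx] <- out$grams[egg_idx] + grams_replaced
  } else {
    egg_row <- out[0, ]
    egg_row[1, "food_id"] <- egg$food_id[1]
    egg_row[1, "name"] <- egg$name[1]
    egg_row[1, "grams"] <- grams_replaced
    egg_row[1, "group"] <- "protein"
    egg_row[1, "protein_subgroup"] <- "eggs"
    if ("mixed_dish" %in% names(egg_row)) egg_row[1, "mixed_dish"] <- FALSE
    if ("menu" %in% names(out)) egg_row[1, "menu"] <- day_foods$menu[1]
    if ("day" %in% names(out)) egg_row[1, "day"] <- day_foods$day[1]
    for (col in dens) egg_row[1, col] <- egg_dens[[col]]
    if ("price_per_100g" %in% names(egg_row) &&
        "price_per_100g" %in% names(egg)) {
      egg_row[1, "price_per_100g"] <- egg$price_per_100g[1]
    }
    out <- dplyr::bind_rows(out, egg_row)
  }
  list(foods = out, delta = delta)
}

#' Substitute one egg per day throughout a menu plan
#'
#' Composes [select_targets()] and [apply_substitution()] over all days.
#' Days without an eligible candidate (or listed in `skip_days`) pass
#' through unchanged, so their daily totals are identical between the two
#' conditions.
#'
#' @inheritParams select_targets
#' @param egg A one-row egg profile, default [default_egg_profile()].
#' @param ... Passed on to [select_targets()].
#' @return An object of class `menu_substitution`: a list with `plan` (the
#'   substituted plan), `records` (one row per day with target, rationale and
#'   `delta_*` nutrient-change columns) and `egg`.
#' @examples
#' cfg <- sim_config(seed = 7)
#' sub <- substitute_plan(generate_plan(cfg))
#' sub$records
#' @export
substitute_plan <- function(plan, egg = default_egg_profile(), ...) {
  plan <- validate_menu_plan(plan)
  records <- select_targets(plan, ...)
  dens <- intersect(.plan_density_cols(), names(plan))
  delta_cols <- paste0("delta_", sub("_per_100g$", "", dens))
  new_days <- list()
  deltas <- list()
  for (i in seq_len(nrow(records))) {
    d <- records$day[i]
    day_foods <- plan[plan$day == d, ]
    if (is.na(records$target_food_id[i])) {
      new_days[[i]] <- day_foods
      deltas[[i]] <- stats::setNames(rep(0, length(dens)),
                                     sub("_per_100g$", "", dens))
    } else {
      res <- apply_substitution(day_foods, records$target_food_id[i], egg,
                                records$grams_replaced[i])
      new_days[[i]] <- res$foods
      deltas[[i]] <- res$delta
    }
  }
  delta_tbl <- dplyr::bind_rows(lapply(deltas, as.list))
  names(delta_tbl) <- paste0("delta_", names(delta_tbl))
  records <- dplyr::bind_cols(records, delta_tbl)
  out_plan <- dplyr::bind_rows(new_days)
  attr(out_plan, "kcal_target") <- attr(plan, "kcal_target")
  structure(list(plan = out_plan, records = records, egg = egg),
            class = "menu_substitution")
}

#' @export
print.menu_substitution <- function(x, ...) {
  n_sub <- sum(!is.na(x$records$target_food_id))
  cat("Egg substitution over", nrow(x$records), "days:", n_sub,
      "substituted,", nrow(x$records) - n_sub, "passed through\n")
  print(dplyr::select(x$records, "day", "target_food_id", "rationale"))
  invisible(x)
}
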