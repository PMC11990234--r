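# Builders and independent oracles shared across test files.

# One menu-plan row with all required columns; densities default to zero.
food_row <- function(day, food_id, grams, group = "other",
                     subgroup = "none", name = food_id,
                     protein_g_per_100g = 0, energy_kcal_per_100g = 100,
                     densities = list()) {
  row <- tibble::tibble(
    menu = "test", day = day, food_id = food_id, name = name,
    grams = grams, group = group, protein_subgroup = subgroup,
    mixed_dish = FALSE, price_per_100g = NA_real_,
    energy_kcal_per_100g = energy_kcal_per_100g,
    protein_g_per_100g = protein_g_per_100g,
    choline_mg_per_100g = 0, potassium_mg_per_100g = 0,
    calcium_mg_per_100g = 0, folate_mcg_per_100g = 0,
    magnesium_mg_per_100g = 0, zinc_mg_per_100g = 0,
    vitamin_d_mcg_per_100g = 0, vitamin_c_mg_per_100g = 0)
  for (nm in names(densities)) row[[nm]] <- densities[[nm]]
  row
}

make_plan <- function(...) dplyr::bind_rows(...)

# A DRI table with the same value for both sexes, for closed-form checks.
equal_sex_dri <- function(value = 100) {
  dri <- default_dri_table()
  dri$value <- value
  dri
}

# Independent brute-force target selection: plain loops, no shared code with
# select_targets(). Ranks every per-day candidate by (variety penalty,
# -protein grams, menu order) and enforces the seafood retention constraint.
oracle_select <- function(plan, grams_replaced = 44, min_grams = 44,
                          seafood_weekly_target = 226.8,
                          kcal_target = 2000) {
  target <- seafood_weekly_target * kcal_target / 2000
  seafood_left <- sum(plan$grams[plan$protein_subgroup == "seafood"])
  used <- character(0)
  out <- data.frame(day = sort(unique(plan$day)),
                    target_food_id = NA_character_,
                    rationale = NA_character_)
  for (k in seq_len(nrow(out))) {
    d <- out$day[k]
    df <- plan[plan$day == d, ]
    df$.ord <- seq_len(nrow(df))
    cand <- df[df$group == "protein" & df$protein_subgroup != "eggs" &
                 df$grams >= min_grams, ]
    best <- NULL
    best_key <- NULL
    for (i in seq_len(nrow(cand))) {
      row <- cand[i, ]
      if (row$protein_subgroup == "seafood" &&
          (seafood_left - grams_replaced) < target) next
      pen <- as.numeric(paste(row$protein_subgroup, row$name,
                              sep = "||") %in% used)
      prot <- row$grams * row$protein_g_per_100g / 100
      key <- c(pen, -prot, row$.ord)
      better <- is.null(best_key) ||
        key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2]) ||
        (key[1] == best_key[1] && key[2] == best_key[2] &&
           key[3] < best_key[3])
      if (better) {
        best <- row
        best_key <- key
      }
    }
    if (is.null(best)) {
      out$rationale[k] <- "no_candidate"
    } else {
      out$target_food_id[k] <- best$food_id
      used <- c(used, paste(best$protein_subgroup, best$name, sep = "||"))
      if (best$protein_subgroup == "seafood") {
        seafood_left <- seafood_left - grams_replaced
      }
    }
  }
  out
}

# Independent daily-total summation: explicit double loop.
oracle_daily_totals <- function(plan, density_col) {
  days <- sort(unique(plan$day))
  vapply(days, function(d) {
    rows <- plan[plan$day == d, ]
    tot <- 0
    for (i in seq_len(nrow(rows))) {
      tot <- tot + rows$grams[i] * rows[[density_col]][i] / 100
    }
    tot
  }, numeric(1))
}

# Textbook t statistics for the oracle comparison in test-stats.R.
oracle_t <- function(x, y, mode) {
  if (mode == "paired") {
    d <- x - y
    n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
    df <- n - 1
  } else if (mode == "pooled") {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    n1 <- length(x); n2 <- length(y)
    v1 <- var(x) / n1; v2 <- var(y) / n2
    t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p = p)
}
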