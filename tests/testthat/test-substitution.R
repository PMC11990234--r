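salmon_beef_day <- function(day = 1) {
  make_plan(
    food_row(day, "salmon", 168, group = "protein", subgroup = "seafood",
             name = "Salmon, cooked", protein_g_per_100g = 25,
             densities = list(vitamin_d_mcg_per_100g = 13)),
    food_row(day, "roast_beef", 120, group = "protein",
             subgroup = "meat_poultry", name = "Roast beef",
             protein_g_per_100g = 26,
             densities = list(choline_mg_per_100g = 80)),
    food_row(day, "broccoli", 150,
             densities = list(vitamin_c_mg_per_100g = 65)))
}

test_that("protein candidates are non-egg protein foods >= 44 g, ordered by protein content", {
  day <- salmon_beef_day()
  cands <- identify_protein_candidates(day)
  expect_equal(cands$food_id, c("salmon", "roast_beef"))
  expect_equal(cands$protein_g, c(168 * 25, 120 * 26) / 100)

  egg_day <- make_plan(
    food_row(1, "egg", 50, group = "protein", subgroup = "eggs",
             protein_g_per_100g = 13),
    food_row(1, "spinach", 80))
  expect_equal(nrow(identify_protein_candidates(egg_day)), 0)

  small_day <- food_row(1, "jerky", 30, group = "protein",
                        subgroup = "meat_poultry", protein_g_per_100g = 30)
  expect_equal(nrow(identify_protein_candidates(small_day)), 0)
})

test_that("seafood is retained when replacing it would break the weekly target", {
  # salmon has the most protein but 168 - 44 < 226.8, so beef is chosen
  plan <- salmon_beef_day()
  rec <- select_targets(plan, kcal_target = 2000)
  expect_equal(rec$target_food_id, "roast_beef")
  expect_equal(rec$rationale, "seafood_retained")

  # plenty of seafood elsewhere in the week: salmon becomes fair game
  plan2 <- make_plan(salmon_beef_day(1),
                     food_row(2, "tuna", 300, group = "protein",
                              subgroup = "seafood",
                              protein_g_per_100g = 24))
  rec2 <- select_targets(plan2, kcal_target = 2000)
  expect_equal(rec2$target_food_id[1], "salmon")
  expect_equal(rec2$rationale[1], "highest_protein")

  # the weekly target scales with the plan's energy level
  rec3 <- select_targets(salmon_beef_day(), kcal_target = 1000)
  expect_equal(rec3$target_food_id, "salmon")
})

test_that("the variety rule deprioritizes repeats of an already-used protein", {
  steak <- function(d) {
    food_row(d, paste0("steak_d", d), 150, group = "protein",
             subgroup = "meat_poultry", name = "Steak-beef",
             protein_g_per_100g = 27)
  }
  plan <- make_plan(
    steak(1),
    steak(2),
    food_row(2, "chicken_lunchmeat", 100, group = "protein",
             subgroup = "meat_poultry",
             name = "Lunchmeats and sausages, chicken",
             protein_g_per_100g = 16))
  rec <- select_targets(plan)
  expect_equal(rec$target_food_id, c("steak_d1", "chicken_lunchmeat"))
  expect_equal(rec$rationale, c("highest_protein", "variety_rule_applied"))

  # soft penalty only: with no alternative the repeat is still selected
  plan2 <- make_plan(steak(1), steak(2))
  rec2 <- select_targets(plan2)
  expect_equal(rec2$target_food_id, c("steak_d1", "steak_d2"))
})

test_that("selection matches the brute-force enumeration oracle on 100 seeded plans", {
  for (seed in 1:100) {
    cfg <- sim_config(seed = seed, protein_items_per_day = 3,
                      seafood_days = 3)
    plan <- generate_plan(cfg)
    got <- select_targets(plan, kcal_target = cfg$kcal_target)
    want <- oracle_select(plan, kcal_target = cfg$kcal_target)
    expect_equal(got$target_food_id, want$target_food_id,
                 label = paste("seed", seed))
  }
})

test_that("apply_substitution conserves grams and yields the closed-form delta", {
  egg <- default_egg_profile()
  egg$choline_mg_per_100g <- 300
  day <- food_row(1, "turkey", 90, group = "protein",
                  subgroup = "meat_poultry", protein_g_per_100g = 29,
                  densities = list(choline_mg_per_100g = 100))
  res <- apply_substitution(day, "turkey", egg)
  expect_equal(res$delta[["choline_mg"]], 0.44 * (300 - 100))
  expect_equal(sum(res$foods$grams), sum(day$grams))
  expect_equal(day$grams, 90) # input untouched

  # identical densities: the swap is nutritionally a no-op
  clone <- day
  clone_egg <- egg
  for (col in grep("_per_100g$", names(day), value = TRUE)) {
    clone_egg[[col]] <- day[[col]]
  }
  res2 <- apply_substitution(clone, "turkey", clone_egg)
  expect_true(all(res2$delta == 0))

  expect_error(apply_substitution(day, "ham", egg), "not found")
  small <- day
  small$grams <- 30
  expect_error(apply_substitution(small, "turkey", egg), "only 30")
})

test_that("an existing egg item absorbs the swap instead of duplicating", {
  egg <- default_egg_profile()
  day <- make_plan(
    food_row(1, "turkey", 90, group = "protein",
             subgroup = "meat_poultry", protein_g_per_100g = 29),
    food_row(1, egg$food_id, 44, group = "protein", subgroup = "eggs"))
  res <- apply_substitution(day, "turkey", egg)
  expect_equal(nrow(res$foods), 2)
  expect_equal(res$foods$grams[res$foods$food_id == egg$food_id], 88)
})

test_that("substitute_plan adds deltas to daily totals and never targets eggs", {
  egg <- default_egg_profile()
  for (seed in c(2, 17, 31)) {
    plan <- generate_plan(sim_config(seed = seed))
    sub <- substitute_plan(plan, egg)
    expect_false(any(sub$records$target_food_id %in%
                       plan$food_id[plan$protein_subgroup == "eggs"]))
    # gram conservation per day, against an independent sum
    before <- tapply(plan$grams, plan$day, sum)
    after <- tapply(sub$plan$grams, sub$plan$day, sum)
    expect_equal(unname(after), unname(before))
    # totals additivity: out = in + delta, nutrient by nutrient
    for (col in c("choline_mg", "vitamin_d_mcg", "zinc_mg")) {
      dcol <- paste0(col, "_per_100g")
      expect_equal(oracle_daily_totals(sub$plan, dcol),
                   oracle_daily_totals(plan, dcol) +
                     sub$records[[paste0("delta_", col)]],
                   tolerance = 1e-12)
    }
    # purity and determinism
    sub2 <- substitute_plan(plan, egg)
    expect_equal(sub2$records, sub$records)
  }
})

test_that("days without an eligible candidate pass through unchanged", {
  veg_plan <- make_plan(food_row(1, "rice", 200), food_row(1, "beans_tiny", 30,
                        group = "protein", subgroup = "legumes_peas_lentils",
                        protein_g_per_100g = 8))
  sub <- substitute_plan(veg_plan)
  expect_equal(sub$records$rationale, "no_candidate")
  expect_equal(as.data.frame(sub$plan), as.data.frame(veg_plan))

  # a per-day skip leaves that day's totals identical across conditions,
  # like the one untouched day in the packaged menus
  plan <- generate_plan(sim_config(seed = 4))
  sub2 <- substitute_plan(plan, skip_days = 6)
  expect_equal(sub2$records$rationale[6], "skipped")
  expect_equal(sum(!is.na(sub2$records$target_food_id)), 6)
  t_in <- plan_daily_totals(plan)
  t_out <- plan_daily_totals(sub2$plan)
  expect_equal(t_out[t_out$day == 6, ], t_in[t_in$day == 6, ])
  expect_false(isTRUE(all.equal(t_out[t_out$day == 1, ],
                                t_in[t_in$day == 1, ])))
})
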