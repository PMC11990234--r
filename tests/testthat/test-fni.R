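test_that("component scores follow the capped percent-of-DRI construction", {
  # the published worked example: 624 mg calcium against the 1300 mg RDA
  expect_identical(component_score(624, 1300, 1300), 48)
  expect_equal(component_score(0, 400, 550), 0)
  expect_equal(component_score(600, 400, 550), 100)
  # HUSS as-given mean choline against the sex-specific AIs
  expect_equal(component_score(386.57, 400, 550), 83.4, tolerance = 0.2 / 83)

  # cap applies per sex before averaging: one sex over, one under
  expect_equal(component_score(10, 8, 12), (100 + 100 * 10 / 12) / 2)
  # which differs from capping the averaged ratio
  expect_false(isTRUE(all.equal(component_score(10, 8, 12),
                                min(100, 100 * mean(c(10 / 8, 10 / 12))))))

  # non-decreasing, piecewise linear, 100 iff amount >= the larger DRI
  amounts <- seq(0, 700, by = 7)
  scores <- component_score(amounts, 400, 550)
  expect_true(all(diff(scores) >= 0))
  expect_true(all(scores[amounts >= 550] == 100))
  expect_true(all(scores[amounts < 550] < 100))

  expect_error(component_score(10, 0, 12), "positive")
  expect_error(component_score(-1, 400, 550), "non-negative")
})

test_that("plan daily totals sum grams x density / 100 over each day", {
  plan <- food_row(1, "eggs", 100,
                   densities = list(choline_mg_per_100g = 300))
  expect_equal(plan_daily_totals(plan)$choline_mg, 300)

  # splitting a food into two half portions leaves totals unchanged
  half <- make_plan(
    food_row(1, "eggs_a", 50, densities = list(choline_mg_per_100g = 300)),
    food_row(1, "eggs_b", 50, densities = list(choline_mg_per_100g = 300)))
  expect_equal(plan_daily_totals(half)$choline_mg, 300)

  plan2 <- generate_plan(sim_config(seed = 21))
  totals <- plan_daily_totals(plan2)
  for (col in fni_nutrients()$density_col) {
    expect_equal(totals[[sub("_per_100g$", "", col)]],
                 oracle_daily_totals(plan2, col))
  }
})

test_that("mean-of-days scoring handles the boundary cases", {
  zeros <- tibble::tibble(day = 1:7,
                          choline_mg = 0, potassium_mg = 0, calcium_mg = 0,
                          folate_mcg = 0, magnesium_mg = 0, zinc_mg = 0,
                          vitamin_d_mcg = 0, vitamin_c_mg = 0)
  res0 <- fni_score(zeros)
  expect_true(all(res0$component$score == 0))
  expect_equal(res0$total, 0)

  # totals pinned at each sex-averaged DRI of an equal-sex table score 100
  dri <- equal_sex_dri(500)
  at_dri <- zeros |> dplyr::mutate(dplyr::across(-day, ~500))
  res1 <- fni_score(at_dri, dri)
  expect_true(all(res1$component$score == 100))
  expect_equal(res1$total, 100)

  expect_error(fni_score(zeros[0, ]), "empty")
  expect_error(fni_score(dplyr::select(zeros, -"zinc_mg")), "zinc_mg")
})

test_that("per-day scoring reports day-level totals with mean and sample SD", {
  huss <- exemplary_totals("HUSS", "as_given")
  res <- fni_score(huss, mode = "per_day")
  # day-1 value frozen from a by-hand computation of the eight components
  # (choline 96.6182, folate 92.15, magnesium 88.7378, the other five at 100)
  expect_equal(res$daily$score[res$daily$day == 1], 97.1883, tolerance = 1e-4)
  expect_equal(res$total, mean(res$daily$score))
  expect_equal(res$sd, sd(res$daily$score))
  expect_true(res$total >= min(res$daily$score))

  # constant days have zero spread
  const <- huss[rep(1, 7), ] |> dplyr::mutate(day = 1:7)
  expect_equal(fni_score(const, mode = "per_day")$sd, 0)

  # the cap makes per-day and mean-of-days differ in general
  expect_false(isTRUE(all.equal(res$total, fni_score(huss)$total)))
})

test_that("a choline-dominant egg never lowers the choline component", {
  for (seed in 1:50) {
    cfg <- sim_config(seed = seed)
    plan <- generate_plan(cfg)
    egg <- default_egg_profile()
    egg$choline_mg_per_100g <- max(plan$choline_mg_per_100g) + 1
    sub <- substitute_plan(plan, egg, kcal_target = cfg$kcal_target)
    before <- fni_score(plan_daily_totals(plan))
    after <- fni_score(plan_daily_totals(sub$plan))
    ch_before <- before$component$score[before$component$nutrient == "choline"]
    ch_after <- after$component$score[after$component$nutrient == "choline"]
    expect_gte(ch_after, ch_before)
  }
})

test_that("tidy and glance expose components and the equal-weight total", {
  res <- fni_score(exemplary_totals("HVEG", "as_given"))
  td <- tidy(res)
  expect_equal(nrow(td), 8)
  expect_true(all(c("nutrient", "unit", "score") %in% names(td)))
  expect_equal(nrow(tidy(res, by_sex = TRUE)), 16)
  gl <- glance(res)
  expect_equal(gl$total, mean(td$score))
  expect_equal(gl$n_days, 7)
})
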