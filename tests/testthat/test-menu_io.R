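test_that("menu plan CSV round-trips and the smallest valid input loads", {
  plan <- food_row(1, "oatmeal", 40,
                   densities = list(choline_mg_per_100g = 7.4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_menu_plan(plan, path)
  got <- read_menu_plan(path)
  expect_equal(length(unique(got$day)), 1)
  expect_equal(as.data.frame(got), as.data.frame(plan))

  # multi-day synthetic plan round-trips field for field
  plan2 <- generate_plan(sim_config(seed = 9))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_menu_plan(plan2, path2)
  got2 <- read_menu_plan(path2)
  attr(plan2, "kcal_target") <- NULL # serialization carries columns only
  expect_equal(as.data.frame(got2), as.data.frame(plan2))
})

test_that("menu plan reader rejects structural violations with context", {
  dup <- make_plan(food_row(1, "rice", 100), food_row(1, "rice", 50))
  expect_error(validate_menu_plan(dup), "Duplicate food_id 'rice'")

  plan <- food_row(1, "rice", 100)
  expect_error(validate_menu_plan(dplyr::select(plan, -"grams")),
               "missing column")
  bad_grams <- plan
  bad_grams$grams <- -5
  expect_error(validate_menu_plan(bad_grams), "day 1.*rice")

  gap_days <- make_plan(food_row(1, "a", 10), food_row(3, "b", 10))
  expect_error(validate_menu_plan(gap_days), "consecutive")

  bad_sub <- plan
  bad_sub$group <- "protein" # subgroup still 'none'
  expect_error(validate_menu_plan(bad_sub), "protein_subgroup")
})

test_that("unknown nutrient columns are dropped with a warning", {
  plan <- food_row(1, "rice", 100)
  plan$selenium_mcg_per_100g <- 5
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(plan, path)
  expect_warning(got <- read_menu_plan(path), "selenium")
  expect_false("selenium_mcg_per_100g" %in% names(got))
})

test_that("packaged daily totals match the printed exemplary-menu values", {
  huss <- exemplary_totals("HUSS", "as_given")
  expect_equal(nrow(huss), 7)
  expect_equal(huss$choline_mg[huss$day == 1], 512.8)
  expect_equal(huss$potassium_mg[huss$day == 1], 3485.1)

  # the one day the substitution left untouched: both conditions identical
  d6_as <- exemplary_totals("DASH", "as_given") |> dplyr::filter(day == 6)
  d6_eg <- exemplary_totals("DASH", "egg_substitution") |>
    dplyr::filter(day == 6)
  expect_equal(d6_as[-2], d6_eg[-2]) # all but the condition label

  hveg <- exemplary_totals("HVEG", "egg_substitution")
  expect_equal(hveg$vitamin_d_mcg[hveg$day == 7], 5.4)

  expect_error(exemplary_totals("HOSS"), "arg")
})

test_that("packaged daily prices match the printed values", {
  huss <- exemplary_prices("HUSS", "as_given")
  expect_equal(huss$price_usd, c(7.6, 7.7, 9.9, 10.6, 10.3, 10.2, 11.0))
  dash <- exemplary_prices("DASH", "egg_substitution")
  expect_equal(dash$price_usd[dash$day == 2], 5.0)
  counts <- exemplary_prices() |> dplyr::count(menu, condition)
  expect_equal(nrow(counts), 8)
  expect_true(all(counts$n == 7))
})

test_that("fixture files are unchanged since transcription", {
  files <- c(
    dri_adolescent_14_18.csv = "4b4e4a128faf71284fb19f4ebb76cff9",
    egg_boiled_reference.csv = "cb4db27298fa02b12bc9dcf758de8caa",
    exemplary_daily_means.csv = "c6cfc814ac31ee9d3212a1a9062ac94d",
    exemplary_prices.csv = "44e885f301c79e80c4a341b9eeb061a8",
    exemplary_totals.csv = "6790e0e4ebe9af54e363fa8ae18eae2a",
    fni_published.csv = "496268964b98209353b61fad983232b3",
    price_summary_published.csv = "bd25a01b19de853e2465c3a27ab89194")
  for (f in names(files)) {
    path <- system.file("extdata", f, package = "fnimenu", mustWork = TRUE)
    expect_equal(unname(tools::md5sum(path)), unname(files[[f]]),
                 label = f)
  }
})

test_that("the default egg profile is a valid 44 g protein food", {
  egg <- default_egg_profile()
  expect_equal(egg$grams, 44)
  expect_equal(egg$protein_subgroup, "eggs")
  expect_equal(egg$price_per_100g, 0.35)
  expect_true(all(unlist(egg[grep("_per_100g$", names(egg))]) >= 0))
})
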