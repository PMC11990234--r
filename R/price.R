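#' Price one day of a menu
#'
#' Daily cost is the sum over foods of `grams / 100 * price`, with prices in
#' as-consumed USD per 100 g. Price lookup order: the price table, then a
#' `price_per_100g` column embedded in the plan (if any), then -- under the
#' `map_then_skip` policy -- the price of the mapped most-similar food.
#' Foods still unpriced are handled by `policy`:
#'
#' * `skip_and_log`: omit from the total and report (the treatment given to
#'   small spice amounts absent from the price database);
#' * `map_then_skip`: consult `mapping` first, then behave as `skip_and_log`;
#' * `error`: abort naming the first unpriced food.
#'
#' @param day_foods Rows of a menu plan for a single day.
#' @param prices A price tibble (`food_id`, `price_usd_per_100g`), or `NULL`
#'   to rely on embedded prices only.
#' @param policy Missing-price policy, see above.
#' @param mapping Optional similarity mapping tibble (`food_id`,
#'   `substitute_food_id`) used by `map_then_skip`.
#' @return A list with `total` (USD) and `missing` (tibble of `day`,
#'   `food_id`, `policy` for every unpriced food).
#' @examples
#' day <- tibble::tibble(day = 1, food_id = "egg", grams = 200)
#' prices <- tibble::tibble(food_id = "egg", price_usd_per_100g = 0.35)
#' price_day(day, prices)$total # 0.70
#' @export
price_day <- function(day_foods, prices = NULL,
                      policy = c("skip_and_log", "map_then_skip", "error"),
                      mapping = NULL) {
  policy <- match.arg(policy)
  day_foods <- tibble::as_tibble(day_foods)
  lookup <- function(id) {
    p <- NA_real_
    if (!is.null(prices)) {
      hit <- match(id, prices$food_id)
      if (!is.na(hit)) p <- prices$price_usd_per_100g[hit]
    }
    if (is.na(p) && "price_per_100g" %in% names(day_foods)) {
      p <- day_foods$price_per_100g[match(id, day_foods$food_id)]
    }
    p
  }
  unit_price <- vapply(day_foods$food_id, lookup, numeric(1))
  if (policy == "map_then_skip" && !is.null(mapping)) {
    for (i in which(is.na(unit_price))) {
      sub_id <- mapping$substitute_food_id[
        match(day_foods$food_id[i], mapping$food_id)]
      if (!is.na(sub_id)) unit_price[i] <- lookup(sub_id)
    }
  }
  miss <- is.na(unit_price)
  if (policy == "error" && any(miss)) {
    rlang::abort(paste0("No price for food '",
                        day_foods$food_id[which(miss)[1]], "'."))
  }
  missing <- tibble::tibble(
    day = if ("day" %in% names(day_foods)) day_foods$day[miss] else
      rep(NA_integer_, sum(miss)),
    food_id = day_foods$food_id[miss],
    policy = rep(policy, sum(miss)))
  total <- sum(day_foods$grams[!miss] * unit_price[!miss] / 100)
  list(total = total, missing = missing)
}

#' Price a whole menu plan
#'
#' @inheritParams price_day
#' @param plan A menu-plan tibble.
#' @return An object of class `price_result`: `daily` (tibble of `day`,
#'   `price_usd`), `mean`, `sd` (sample, n-1), and `missing` (log of
#'   unpriced items).
#' @export
price_plan <- function(plan, prices = NULL,
                       policy = c("skip_and_log", "map_then_skip", "error"),
                       mapping = NULL) {
  policy <- match.arg(policy)
  plan <- tibble::as_tibble(plan)
  days <- sort(unique(plan$day))
  per_day <- purrr::map(days, function(d) {
    price_day(plan[plan$day == d, ], prices, policy, mapping)
  })
  daily <- tibble::tibble(day = days,
                          price_usd = vapply(per_day, `[[`, numeric(1),
                                             "total"))
  structure(
    list(daily = daily,
         mean = mean(daily$price_usd),
         sd = stats::sd(daily$price_usd),
         missing = dplyr::bind_rows(lapply(per_day, `[[`, "missing"))),
    class = "price_result")
}

#' @export
print.price_result <- function(x, ...) {
  cat("Menu price over", nrow(x$daily), "days: mean",
      formatC(x$mean, format = "f", digits = 2), "USD, SD",
      formatC(x$sd, format = "f", digits = 2), "USD\n")
  if (nrow(x$missing) > 0) {
    cat("Unpriced items:", nrow(x$missing), "\n")
  }
  invisible(x)
}

#' Mean and SD of the packaged daily menu prices
#'
#' Recomputes the daily mean and sample SD from the seven transcribed daily
#' prices for every menu-condition pair, the quantities printed as
#' "Daily mean (SD)".
#'
#' @return A tibble with `menu`, `condition`, `mean_usd`, `sd_usd`, `n_days`.
#' @examples
#' summarize_price_fixtures()
#' @export
summarize_price_fixtures <- function() {
  exemplary_prices() |>
    dplyr::summarise(mean_usd = mean(.data$price_usd),
                     sd_usd = stats::sd(.data$price_usd),
                     n_days = dplyr::n(),
                     .by = c("menu", "condition"))
}
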