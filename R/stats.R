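#' Bonferroni-adjusted significance threshold
#'
#' @param base_alpha Family-wise error rate, in (0, 1).
#' @param n_comparisons Number of comparisons in the family (>= 1).
#' @return `base_alpha / n_comparisons`, exactly.
#' @examples
#' bonferroni_alpha(0.05, 4)   # 0.0125
#' bonferroni_alpha(0.05, 256) # ~0.000195
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_comparisons = 1) {
  stopifnot(is.numeric(base_alpha), length(base_alpha) == 1,
            base_alpha > 0, base_alpha < 1,
            is.numeric(n_comparisons), length(n_comparisons) == 1,
            n_comparisons >= 1, n_comparisons == as.integer(n_comparisons))
  base_alpha / n_comparisons
}

#' Two-sided t test between two conditions
#'
#' Thin wrapper around [stats::t.test()] returning a tidy one-row result and
#' handling the degenerate inputs that arise with menu data: in paired mode
#' an all-zero difference vector returns `statistic = 0, p = 1` by
#' convention, and a constant nonzero difference returns `p = 0` (signed
#' infinite statistic). Modes: `"welch"` (unpaired, unequal variances, the
#' default), `"paired"`, `"pooled"` (unpaired, pooled variance).
#'
#' @param x,y Numeric vectors (length >= 2; equal lengths for paired mode).
#' @param mode Test mode, see above.
#' @param alpha Significance threshold recorded in the result (use
#'   [bonferroni_alpha()] for adjusted families).
#' @param label Optional label carried into the result.
#' @return A one-row tibble: `label`, `statistic`, `df`, `p_value`,
#'   `alpha_adjusted`, `significant`, `test_mode`.
#' @export
menu_t_test <- function(x, y, mode = c("welch", "paired", "pooled"),
                        alpha = 0.05, label = "") {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (mode == "paired" && length(x) != length(y)) {
    rlang::abort("Paired mode requires equal-length vectors.")
  }
  res <- if (mode == "paired") {
    d <- x - y
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        list(statistic = 0, parameter = length(d) - 1, p.value = 1)
      } else {
        list(statistic = sign(mean(d)) * Inf, parameter = length(d) - 1,
             p.value = 0)
      }
    } else {
      stats::t.test(x, y, paired = TRUE)
    }
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) {
        list(statistic = 0, parameter = length(x) + length(y) - 2,
             p.value = 1)
      } else {
        list(statistic = sign(mean(x) - mean(y)) * Inf,
             parameter = length(x) + length(y) - 2, p.value = 0)
      }
    } else {
      stats::t.test(x, y, var.equal = (mode == "pooled"))
    }
  }
  tibble::tibble(
    label = label,
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    alpha_adjusted = alpha,
    significant = res$p.value < alpha,
    test_mode = mode)
}

#' Compare two menu conditions across the three reported families
#'
#' Runs the comparison scheme used for the exemplary menus:
#'
#' * **nutrient** family: one t test per tracked nutrient between the two
#'   conditions' daily series. Following the published counting scheme the
#'   series comprises the seven daily values plus their mean (eight values
#'   per condition), and the threshold is `base_alpha / 256` (8 nutrients x
#'   8 "days" x 4 menus).
#' * **fni** family: per-day total FNI scores, threshold `base_alpha / 4`.
#' * **price** family: daily prices (when supplied), threshold
#'   `base_alpha / 4`.
#'
#' @param totals_a,totals_b Totals tibbles for the two conditions (e.g.
#'   [exemplary_totals()] as given / with substitution), with matching days.
#' @param prices_a,prices_b Optional numeric vectors of daily prices.
#' @param dri DRI table for the FNI family.
#' @param test_mode Passed to [menu_t_test()].
#' @param base_alpha Family-wise error rate before adjustment.
#' @param n_nutrient_comparisons,n_summary_comparisons Bonferroni divisors
#'   for the nutrient and the FNI/price families (defaults 256 and 4).
#' @param printed_thresholds Use the truncated thresholds as printed (0.0001
#'   and 0.01) instead of the exact divisions; conclusions are unchanged for
#'   the packaged data.
#' @param include_daily_mean Append each nutrient's mean to its daily series
#'   (the published counting scheme). Set `FALSE` to test the seven dailies
#'   alone.
#' @return A tibble of [menu_t_test()] rows with a leading `family` column.
#' @export
compare_conditions <- function(totals_a, totals_b,
                               prices_a = NULL, prices_b = NULL,
                               dri = default_dri_table(),
                               test_mode = c("welch", "paired", "pooled"),
                               base_alpha = 0.05,
                               n_nutrient_comparisons = 256,
                               n_summary_comparisons = 4,
                               printed_thresholds = FALSE,
                               include_daily_mean = TRUE) {
  test_mode <- match.arg(test_mode)
  cols <- .amount_cols()
  stopifnot(all(cols %in% names(totals_a)), all(cols %in% names(totals_b)))
  if (nrow(totals_a) != nrow(totals_b)) {
    rlang::abort("Conditions have mismatched day counts.")
  }
  alpha_nutrient <- if (printed_thresholds) 1e-4 else
    bonferroni_alpha(base_alpha, n_nutrient_comparisons)
  alpha_summary <- if (printed_thresholds) 0.01 else
    bonferroni_alpha(base_alpha, n_summary_comparisons)

  series <- function(v) if (include_daily_mean) c(v, mean(v)) else v
  nutrient_rows <- purrr::map(cols, function(col) {
    menu_t_test(series(totals_a[[col]]), series(totals_b[[col]]),
                mode = test_mode, alpha = alpha_nutrient, label = col)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(family = "nutrient", .before = 1)

  fni_a <- fni_score(totals_a, dri, mode = "per_day")
  fni_b <- fni_score(totals_b, dri, mode = "per_day")
  fni_rows <- menu_t_test(fni_a$daily$score, fni_b$daily$score,
                          mode = test_mode, alpha = alpha_summary,
                          label = "total_fni") |>
    dplyr::mutate(family = "fni", .before = 1)

  out <- dplyr::bind_rows(nutrient_rows, fni_rows)
  if (!is.null(prices_a) && !is.null(prices_b)) {
    price_rows <- menu_t_test(prices_a, prices_b, mode = test_mode,
                              alpha = alpha_summary, label = "daily_price") |>
      dplyr::mutate(family = "price", .before = 1)
    out <- dplyr::bind_rows(out, price_rows)
  }
  out
}
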