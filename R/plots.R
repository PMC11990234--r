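#' Plot FNI component scores
#'
#' Bar chart of the eight component scores, optionally split by sex, with
#' the equal-weight total as a reference line.
#'
#' @param object An `fni_result`.
#' @param by_sex Facet by sex instead of plotting sex-averaged scores.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fni_result <- function(object, by_sex = FALSE, ...) {
  if (by_sex) {
    dat <- object$component_by_sex
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$nutrient,
                                           y = .data$score,
                                           fill = .data$sex)) +
      ggplot2::geom_col(position = "dodge")
  } else {
    dat <- object$component
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$nutrient,
                                           y = .data$score)) +
      ggplot2::geom_col(fill = "steelblue")
  }
  p +
    ggplot2::geom_hline(yintercept = object$total, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "FNI component score",
                  title = paste0("Food Nutrient Index (total ",
                                 formatC(object$total, format = "f",
                                         digits = 1), ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot daily menu prices
#'
#' @param object A `price_result`.
#' @param ... Unused.
#' @return A ggplot object with daily prices and the mean as a dashed line.
#' @export
autoplot.price_result <- function(object, ...) {
  ggplot2::ggplot(object$daily, ggplot2::aes(x = .data$day,
                                             y = .data$price_usd)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$mean, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$daily$day) +
    ggplot2::labs(x = "Menu day", y = "Daily price (USD)",
                  title = sprintf("Mean daily price %.2f USD (SD %.2f)",
                                  object$mean, object$sd)) +
    ggplot2::theme_minimal()
}

#' Plot per-day nutrient changes from an egg substitution
#'
#' @param object A `menu_substitution`.
#' @param nutrients Nutrient keys to show (default choline and vitamin D,
#'   the components the substitution moves most).
#' @param ... Unused.
#' @return A ggplot object of per-day deltas, faceted by nutrient.
#' @export
autoplot.menu_substitution <- function(object,
                                       nutrients = c("choline", "vitamin_d"),
                                       ...) {
  reg <- dplyr::filter(fni_nutrients(), .data$nutrient %in% nutrients)
  cols <- paste0("delta_", reg$amount_col)
  dat <- object$records |>
    dplyr::select("day", tidyselect::all_of(cols)) |>
    tidyr::pivot_longer(-"day", names_to = "nutrient",
                        values_to = "delta") |>
    dplyr::mutate(nutrient = sub("^delta_", "", .data$nutrient))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$day),
                                    y = .data$delta)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~nutrient, scales = "free_y") +
    ggplot2::labs(x = "Menu day", y = "Daily change (nutrient units)",
                  title = "Nutrient change from the daily egg substitution") +
    ggplot2::theme_minimal()
}
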