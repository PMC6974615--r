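#' Plot a per-class stratification
#'
#' Two aligned panels: the number of included diseases per prevalence class,
#' and the per-class patient-burden range (minimum to maximum bound, per
#' 100,000).
#'
#' @param object An `rd_strata` tibble from [stratify()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rd_strata
#' @export
autoplot.rd_strata <- function(object, ...) {
  cls <- prevalence_classes()
  df <- as_tibble(object) |>
    mutate(class_label = factor(.data$class_label,
                                levels = includable_classes(),
                                labels = cls$pretty[match(includable_classes(),
                                                          cls$class_label)]))
  counts <- df |>
    mutate(panel = "Included diseases", value = .data$n_diseases,
           ymin = NA_real_, ymax = NA_real_)
  burden <- df |>
    mutate(panel = "Patient burden (per 100,000)",
           value = (.data$min_per_100k + .data$max_per_100k) / 2,
           ymin = .data$min_per_100k, ymax = .data$max_per_100k)
  dat <- bind_rows(counts, burden)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class_label)) +
    ggplot2::geom_col(data = counts, ggplot2::aes(y = .data$value),
                      fill = "steelblue") +
    ggplot2::geom_pointrange(
      data = burden,
      ggplot2::aes(y = .data$value, ymin = .data$ymin, ymax = .data$ymax),
      colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "Point-prevalence class", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the component decomposition of a bound estimate
#'
#' Stacked contributions of the three evidence groups to the minimum and
#' maximum cumulative point-prevalence bound.
#'
#' @param object A `bound_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bound_estimate
#' @export
autoplot.bound_estimate <- function(object, ...) {
  df <- object$components |>
    tidyr::pivot_longer(c("min_per_100k", "max_per_100k"),
                        names_to = "bound", values_to = "per_100k") |>
    mutate(bound = ifelse(.data$bound == "min_per_100k",
                          "Minimum", "Maximum"),
           bound = factor(.data$bound, levels = c("Minimum", "Maximum")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bound, y = .data$per_100k,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Cumulative point prevalence per 100,000",
                  fill = "Evidence group") +
    ggplot2::theme_minimal()
}
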