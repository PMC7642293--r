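# ggplot2 displays for the main result types.

#' Volcano plot of a co-IP enrichment result
#'
#' Log2 fold change (IP vs IgG) against -log10 adjusted p-value; when the
#' significance curve has been applied, significant proteins are highlighted
#' and the curve drawn.
#'
#' @param object A `kd_enrichment` tibble ([enrichment_test()], optionally
#'   after [significance_curve()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.kd_enrichment <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$log2fc, y = -log10(.data$p_adj)))
  if ("significant" %in% names(object)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                                 alpha = 0.6) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"))
    curve <- attr(object, "curve")
    if (!is.null(curve)) {
      xs <- seq(curve$fc0 + 0.01, max(abs(object$log2fc), curve$fc0 + 1),
                length.out = 200)
      ys <- -log10(curve$p0) + curve$c / (xs - curve$fc0)
      cdat <- tibble(x = c(-rev(xs), NA, xs), y = c(rev(ys), NA, ys))
      p <- p + ggplot2::geom_line(data = cdat, ggplot2::aes(.data$x, .data$y),
                                  linetype = "dashed", colour = "grey30",
                                  na.rm = TRUE)
    }
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.6)
  }
  p + ggplot2::labs(x = "log2 fold change (IP vs IgG)",
                    y = expression(-log[10] ~ "adjusted p"))
}

#' Signature-score distributions by disease state
#'
#' @param scores Tibble from [score_cohort()].
#' @param annotation Tibble with `sample` and `state`.
#' @return A ggplot object (boxplots of rescaled scores per state, points
#'   overlaid).
#' @export
plot_score_distribution <- function(scores, annotation) {
  d <- dplyr::inner_join(scores, annotation, by = "sample") |>
    dplyr::mutate(state = factor(.data$state, cohort_states()))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$rescaled_score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "rescaled signature score")
}

#' Kaplan-Meier step curves
#'
#' @param km Result of [km_logrank()].
#' @return A ggplot object.
#' @export
plot_km_curves <- function(km) {
  start <- km$curves |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  d <- dplyr::bind_rows(start, km$curves)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", km$test$p.value))
}
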