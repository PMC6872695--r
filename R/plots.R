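#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit survival estimate, with censoring
#' ticks.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- rbind(
    tibble(time = 0, survival = 1, n_censor = 0),
    object[c("time", "survival", "n_censor")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df[df$n_censor > 0, ], shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves for low/high risk groups
#'
#' @param time,event Survival data, see [km_estimate()].
#' @param group `"low"`/`"high"` labels (e.g. from [dichotomize()]).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_km_groups <- function(time, event, group, title = NULL) {
  km <- purrr::imap_dfr(split(seq_along(time), group), function(idx, g) {
    cur <- km_estimate(time[idx], event[idx])
    dplyr::mutate(
      rbind(tibble(time = 0, n_risk = length(idx), n_event = 0,
                   n_censor = 0, survival = 1), cur),
      group = g)
  })
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_color_manual(values = c(high = "red", low = "blue")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  title = title, color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cutoff scan
#'
#' Log-rank chi-square as a function of the candidate cutoff, with the
#' selected maximum marked.
#'
#' @param object A `cutoff_result` from [optimal_cutoff()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cutoff_result
#' @export
autoplot.cutoff_result <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$cutoff, y = .data$chi_square)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2,
                        color = "red") +
    ggplot2::labs(x = object$feature_name, y = "Log-rank chi-square",
                  subtitle = "Maximally selected statistic: naive p is biased") +
    ggplot2::theme_minimal()
}

#' Plot a genomic x PET correlation grid
#'
#' Tile plot of Spearman rho for each genomic-PET feature pair, with
#' the per-cell rho printed.
#'
#' @param object A `correlation_grid` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_grid
#' @export
autoplot.correlation_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$feature_b,
                                       y = .data$feature_a,
                                       fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "PET feature", y = "Genomic feature",
                  fill = "Spearman rho") +
    ggplot2::theme_minimal()
}
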