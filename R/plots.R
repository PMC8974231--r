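#' Plot a utilization or risk raster
#'
#' @param object a `ud_raster` or `risk_surface`.
#' @param trim drop cells below this fraction of the maximum (declutters
#'   the tail of the distribution).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ud_raster <- function(object, trim = 1e-4, ...) {
  d <- tidy(object)
  d <- filter(d, .data$value > trim * max(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "use") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s (%s)", object$group_id, object$interval),
      x = "x (m)", y = "y (m)"
    )
}

#' Plot the motion-variance series of each group
#'
#' @param mv output of [dynamic_variance()].
#' @return a ggplot, one panel per group.
#' @export
plot_motion_variance <- function(mv) {
  ggplot2::ggplot(mv, ggplot2::aes(.data$t, .data$sigma2, group = .data$burst)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~group_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Brownian motion variance")
}

#' Forest plot of fixed-effect estimates
#'
#' @param fit an `nb_glmm` (or other fit with a coefficient table).
#' @param intercept include the intercept row.
#' @return a ggplot of estimates with 95% Wald intervals.
#' @export
plot_coefficients <- function(fit, intercept = FALSE) {
  cf <- fit$coefficients
  if (!intercept) cf <- filter(cf, .data$term != "(Intercept)")
  cf <- mutate(cf, term = factor(.data$term, levels = rev(.data$term[order(term_rank(.data$term))])))
  ggplot2::ggplot(cf, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(x = "estimate (log scale)", y = NULL)
}

#' Plot simulated versus observed response distributions
#'
#' Faceted by the goodness-of-fit grouping (e.g. season x vegetation);
#' observed values in blue, model simulations in orange.
#'
#' @param object a [simulate_gof()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gof_simulation <- function(object, ...) {
  if (object$n_sims == 0) abort("no simulations to plot (n_sims = 0)")
  obs <- tibble(
    value = object$observed, group = object$groups, what = "observed"
  )
  sim <- tibble(
    value = as.vector(object$sims),
    group = rep(object$groups, object$n_sims), what = "simulated"
  )
  ggplot2::ggplot(
    bind_rows(obs, sim),
    ggplot2::aes(log1p(.data$value), colour = .data$what)
  ) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_colour_manual(values = c(observed = "#2166ac", simulated = "#e08214")) +
    ggplot2::labs(x = "log(1 + response)", y = "density", colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
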