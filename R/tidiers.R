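#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    in_levy_band = x$in_levy_band, n_bins = nrow(x$points)
  )
}

#' @export
tidy.forage_fit <- function(x, ...) {
  tibble(
    term = c("w_info", "w_rew", "w_prox",
             "sigma_ambiguity", "sigma_reward", "sigma_proximity"),
    estimate = c(x$weights$info, x$weights$rew, x$weights$prox,
                 x$kernels$ambiguity, x$kernels$reward, x$kernels$proximity),
    unit = c(rep("", 3), rep(x$kernels$units, 3))
  )
}

#' @export
glance.forage_fit <- function(x, ...) {
  tibble(
    loglik = x$loglik, n_terms = x$n_terms,
    n_grid_cells = if (is.null(x$grid_table)) NA_integer_ else nrow(x$grid_table)
  )
}

#' @export
tidy.forage_boot <- function(x, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(x)[c("w_info", "w_rew", "w_prox")],
    dplyr::everything(), names_to = "term", values_to = "value"
  )
  long %>%
    group_by(.data$term) %>%
    summarise(
      estimate = stats::median(.data$value),
      conf.low = stats::quantile(.data$value, 0.025),
      conf.high = stats::quantile(.data$value, 0.975),
      .groups = "drop"
    )
}

#' @export
glance.forage_boot <- function(x, ...) {
  tibble(
    n_subsets = attr(x, "n_subsets"), fraction = attr(x, "fraction"),
    n_completed = nrow(x)
  )
}

#' @export
autoplot.power_law_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$bin_center, y = .data$density)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept / log(10),
                         slope = object$slope) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "step size (m)", y = "probability density",
      title = sprintf("log-log slope %.2f (Levy band: %s)", object$slope,
                      if (object$in_levy_band) "inside" else "outside")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.forage_boot <- function(object, ...) {
  df <- as_tibble(object) %>%
    arrange(.data$w_prox) %>%
    mutate(rank = dplyr::row_number()) %>%
    tidyr::pivot_longer(c("w_info", "w_rew", "w_prox"),
                        names_to = "weight", values_to = "value") %>%
    mutate(weight = factor(.data$weight, c("w_info", "w_rew", "w_prox")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                   fill = .data$weight)) +
    ggplot2::geom_col(position = "stack", width = 1) +
    ggplot2::labs(x = "bootstrap subset (sorted by proximity weight)",
                  y = "weight", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.session_log <- function(object, ...) {
  grid <- session_grid(object)
  piles <- pile_coords(grid)
  path <- piles[object$pile_id + 1L, ]
  path$step <- object$step
  path$found <- object$reward_count
  ggplot2::ggplot(piles, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 21, colour = "grey70") +
    ggplot2::geom_path(data = path, colour = "steelblue") +
    ggplot2::geom_point(data = path[path$found > 0, ],
                        ggplot2::aes(size = .data$found), colour = "purple") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", size = "items") +
    ggplot2::theme_minimal()
}
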