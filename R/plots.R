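#' Plot model-predicted rating distributions
#'
#' Probability of each rating per delay and noise condition under a
#' parameter set, the model analogue of a per-condition rating histogram.
#'
#' @param params A [model_params()] object with `n_yes` set.
#' @param delay_s Delays to display, seconds.
#' @inheritParams place_criteria
#' @return A ggplot object.
#' @export
plot_rating_probabilities <- function(params,
                                      delay_s = c(0, 0.07, 0.1, 0.2),
                                      d_max = 0.2,
                                      placement = c("per_side",
                                                    "shared_max")) {
  placement <- match.arg(placement)
  probs <- rating_probabilities(params, delay_s, c("low", "high"), d_max,
                                placement) |>
    dplyr::mutate(delay = factor(paste0(.data$delay_s * 1000, " ms"),
                                 levels = paste0(sort(unique(delay_s)) *
                                                   1000, " ms")))
  ggplot2::ggplot(probs, ggplot2::aes(x = .data$rating, y = .data$prob,
                                      fill = .data$noise)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~delay, nrow = 1) +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    ggplot2::labs(x = "Agency rating", y = "Probability", fill = "Noise",
                  title = paste(params$model, "model")) +
    ggplot2::theme_minimal()
}

#' Plot rating criteria on the internal-signal axis
#'
#' Internal-signal densities per delay with the model's rating criteria
#' overlaid, one panel per noise condition. Shows how Second-order criteria
#' spread with the condition's noise while First-order criteria shift only
#' through the scale-range padding.
#'
#' @inheritParams plot_rating_probabilities
#' @return A ggplot object.
#' @export
plot_criteria <- function(params, delay_s = c(0, 0.07, 0.1, 0.2),
                          d_max = 0.2,
                          placement = c("per_side", "shared_max")) {
  placement <- match.arg(placement)
  crit <- place_criteria(params, c("low", "high"), d_max, placement) |>
    dplyr::filter(is.finite(.data$position_s))
  dens <- purrr::pmap_dfr(
    tidyr::expand_grid(noise = c("low", "high"), delay_s = delay_s),
    function(noise, delay_s) {
      sg <- sigma_for(params, noise)
      x <- seq(delay_s - 3.5 * sg, delay_s + 3.5 * sg, length.out = 200)
      tibble::tibble(noise = noise, delay_s = delay_s, x = x,
                     density = stats::dnorm(x, delay_s, sg))
    })
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                     group = .data$delay_s)) +
    ggplot2::geom_line(ggplot2::aes(colour = factor(.data$delay_s * 1000))) +
    ggplot2::geom_vline(data = crit,
                        ggplot2::aes(xintercept = .data$position_s),
                        linetype = "dashed", alpha = 0.6) +
    ggplot2::facet_wrap(~noise, ncol = 1) +
    ggplot2::labs(x = "Internal signal (s)", y = "Density",
                  colour = "Delay (ms)",
                  title = paste(params$model, "criteria")) +
    ggplot2::theme_minimal()
}

#' Model-fit, model-selection and recovery autoplots
#' @param object A fitted/result object.
#' @param data Optional trial table to overlay observed frequencies.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot joa_fit
#' @export
autoplot.joa_fit <- function(object, data = NULL, ...) {
  p <- plot_rating_probabilities(object$params, d_max = object$d_max,
                                 placement = object$placement)
  if (!is.null(data)) {
    obs <- data |>
      dplyr::count(.data$noise, .data$delay_ms, .data$joa) |>
      dplyr::group_by(.data$noise, .data$delay_ms) |>
      dplyr::mutate(prob = .data$n / sum(.data$n),
                    delay = factor(paste0(.data$delay_ms, " ms"),
                                   levels = levels(p$data$delay))) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = .data$joa, y = .data$prob, group = .data$noise),
      position = ggplot2::position_dodge(width = 0.9), size = 1
    )
  }
  p
}

#' @rdname autoplot.joa_fit
#' @method autoplot joa_bms
#' @export
autoplot.joa_bms <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("expected_freq", "pep"), names_to = "quantity")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~quantity) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Random-effects model selection") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.joa_fit
#' @method autoplot joa_recovery
#' @export
autoplot.joa_recovery <- function(object, ...) {
  if (object$type == "model") {
    d <- object$confusion |>
      dplyr::group_by(.data$generating) |>
      dplyr::mutate(prop = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    ggplot2::ggplot(d, ggplot2::aes(x = .data$winner, y = .data$generating,
                                    fill = .data$prop)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop))) +
      ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                   limits = c(0, 1)) +
      ggplot2::labs(x = "BIC winner", y = "Generating model",
                    fill = "Proportion", title = "Model recovery") +
      ggplot2::theme_minimal()
  } else {
    est <- dplyr::filter(object$estimates, !.data$failed)
    truth <- tidy_params(object$truth)
    ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate)) +
      ggplot2::geom_histogram(bins = 20) +
      ggplot2::geom_vline(data = truth,
                          ggplot2::aes(xintercept = .data$true),
                          colour = "red", linetype = "dashed") +
      ggplot2::facet_wrap(~term, scales = "free") +
      ggplot2::labs(x = "Estimate", y = "Simulations",
                    title = "Parameter recovery") +
      ggplot2::theme_minimal()
  }
}
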