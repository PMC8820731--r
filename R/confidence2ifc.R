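#' 2IFC decision variable
#'
#' Draw the internal difference signal for a two-interval forced-choice
#' agency discrimination: `y ~ Normal(delta, sigma)` where `delta = d1 - d2`
#' is the signed difference between the two intervals' delays (one of them is
#' always zero) and `sigma` is the task-specific spread of the noise
#' condition. Any factor from combining two noisy intervals into one
#' comparison is absorbed into `sigma`. The observer responds "interval 2 had
#' more agency" when `y` exceeds the decision criterion (interval 1's
#' perceived delay was larger).
#'
#' @param delta Signed delay difference(s) `d1 - d2`, seconds.
#' @param sigma Spread of the difference signal, seconds (> 0).
#' @param seed Optional integer seed for a reproducible draw.
#' @return Numeric draws, one per element of `delta`.
#' @examples
#' decision_variable_2ifc(rep(0.1, 5), 0.19, seed = 1)
#' @export
decision_variable_2ifc <- function(delta, sigma, seed = NULL) {
  if (any(sigma <= 0)) stop("`sigma` must be positive.", call. = FALSE)
  draw <- function() stats::rnorm(length(delta), mean = delta, sd = sigma)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# map (response_interval, confidence) to a 12-bin index; bins 1..6 are
# response "interval 1" with confidence 6..1, bins 7..12 response
# "interval 2" with confidence 1..6
bin_index_2ifc <- function(response_interval, confidence) {
  ifelse(response_interval == 2L, 6L + confidence, 7L - confidence)
}

# signed difference d1 - d2 in seconds for a confidence-trial table
delta_2ifc <- function(data) {
  ifelse(data$delayed_interval == 1L, data$delay_ms, -data$delay_ms) / 1000
}

#' Log-likelihood of a 2IFC confidence table
#'
#' Multinomial log-likelihood of observed (response, confidence) pairs under
#' the 12-bin variant of a model. Each trial's signed delay difference
#' `delta` (positive when interval 1 carried the delay) defines a
#' Normal(delta, sigma) difference signal; the probability of the observed
#' pair is the mass of its bin between the criteria of
#' [place_criteria_2ifc()]. Staircased designs make `delta` vary by trial;
#' trials with identical `delta` are grouped purely as an optimisation.
#'
#' @param data A data frame with columns `noise`, `delayed_interval` (1/2),
#'   `delay_ms` (> 0), `response_interval` (1/2), `confidence` (1..6).
#' @param params A [model_params()] object (`n_yes` ignored).
#' @param delta_max First-order scale anchor, seconds; defaults to the
#'   largest `abs(delta)` in `data`.
#' @param prob_floor Lower bound applied to bin masses before logging.
#' @return The log-likelihood in nats.
#' @export
loglik_2ifc <- function(data, params, delta_max = NULL, prob_floor = 1e-300) {
  stopifnot(is.data.frame(data))
  need <- c("noise", "delayed_interval", "delay_ms", "response_interval",
            "confidence")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("Missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0) stop("Empty trial table.", call. = FALSE)
  check_noise(data$noise)
  if (!all(data$confidence %in% 1:6))
    stop("`confidence` values must be integers in 1..6.", call. = FALSE)
  delta <- delta_2ifc(data)
  if (is.null(delta_max)) delta_max <- max(abs(delta))
  bin <- bin_index_2ifc(data$response_interval, data$confidence)
  ll <- 0
  for (nz in unique(data$noise)) {
    sg <- sigma_for(params, nz)
    g <- gamma_2ifc(params, sg, delta_max)
    sel <- data$noise == nz
    deltas <- sort(unique(delta[sel]))
    pm <- bin_prob_matrix(g, deltas, sg)          # 12 x n_deltas
    counts <- table(factor(bin[sel], levels = 1:12),
                    factor(delta[sel], levels = deltas))
    ll <- ll + sum(counts * log(pmax(pm, prob_floor)))
  }
  ll
}
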