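# probability mass of each rating bin given true delay d and spread sigma;
# gamma is the full boundary vector; returns matrix [bins x length(d)]
bin_prob_matrix <- function(gamma, d, sigma) {
  p <- stats::pnorm(outer(gamma, d, "-") / sigma)
  p[-1L, , drop = FALSE] - p[-length(gamma), , drop = FALSE]
}

#' Rating probabilities under a generative model
#'
#' For each combination of true delay and noise condition, the probability of
#' each rating 1..6: the internal signal is Normal(delay, sigma of the
#' condition), and the probability of rating `r` is the Normal mass between
#' the criteria bounding its bin. Works for both models -- they differ only
#' in where [place_criteria()] puts the boundaries.
#'
#' @param params A [model_params()] object with `n_yes` set.
#' @param delay_s Numeric vector of true delays, seconds (>= 0).
#' @param noise Character vector of noise conditions to evaluate.
#' @inheritParams place_criteria
#' @return A tibble with columns `delay_s`, `noise`, `rating` (1..6), `prob`.
#'   Within each `(delay_s, noise)` cell the probabilities sum to 1.
#' @examples
#' rating_probabilities(representative_params("second_order"), delay_s = 0)
#' @export
rating_probabilities <- function(params, delay_s, noise = c("low", "high"),
                                 d_max = 0.2,
                                 placement = c("per_side", "shared_max")) {
  placement <- match.arg(placement)
  check_noise(noise)
  if (any(delay_s < 0)) stop("`delay_s` must be non-negative.", call. = FALSE)
  purrr::map_dfr(noise, function(nz) {
    sg <- sigma_for(params, nz)
    g <- gamma_agency(params, sg, d_max, placement)
    pm <- bin_prob_matrix(g, delay_s, sg)   # 6 x n_delays, bin 1 leftmost
    d_col <- rep(delay_s, each = 6L)
    r_col <- rep(6:1, times = length(delay_s))
    tibble::tibble(delay_s = d_col, noise = nz, rating = r_col,
                   prob = as.vector(pm))
  })
}

#' Log-likelihood of an agency-rating table
#'
#' Multinomial log-likelihood of observed 6-point agency ratings under a
#' model: trials are aggregated into (delay, noise, rating) cells and the
#' cell counts scored against [rating_probabilities()]. Probabilities are
#' floored at `prob_floor` before taking logs so that a rating placed in a
#' numerically empty bin yields a large finite penalty rather than `-Inf`.
#'
#' @param data A data frame with columns `noise` (`"low"`/`"high"`),
#'   `delay_ms`, and `joa` (integer 1..6). Delays are converted to seconds
#'   internally.
#' @inheritParams rating_probabilities
#' @param prob_floor Lower bound applied to bin probabilities before logging.
#' @return The log-likelihood in nats (a single number).
#' @examples
#' dat <- simulate_agency_session(representative_params("second_order"),
#'                                seed = 1)
#' loglik_agency(dat, representative_params("second_order"))
#' @export
loglik_agency <- function(data, params, d_max = 0.2,
                          placement = c("per_side", "shared_max"),
                          prob_floor = 1e-300) {
  placement <- match.arg(placement)
  stopifnot(is.data.frame(data))
  need <- c("noise", "delay_ms", "joa")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("Missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0) stop("Empty trial table.", call. = FALSE)
  check_noise(data$noise)
  if (!all(data$joa %in% 1:6))
    stop("`joa` values must be integers in 1..6.", call. = FALSE)
  ll <- 0
  for (nz in unique(data$noise)) {
    sg <- sigma_for(params, nz)
    g <- gamma_agency(params, sg, d_max, placement)
    sub <- data[data$noise == nz, ]
    delays <- sort(unique(sub$delay_ms)) / 1000
    pm <- bin_prob_matrix(g, delays, sg)          # bins left-to-right
    pm <- pm[6:1, , drop = FALSE]                 # row r = rating r
    counts <- table(factor(sub$joa, levels = 1:6),
                    factor(sub$delay_ms / 1000, levels = delays))
    ll <- ll + sum(counts * log(pmax(pm, prob_floor)))
  }
  ll
}
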