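#' Agency-session trial design
#'
#' Lay out a full agency-rating session: the four programmed delays (0, 70,
#' 100, 200 ms, so a quarter of trials are synchronous) fully crossed with
#' the two sensory-noise conditions, `trials_per_cell` trials per cell,
#' divided into blocks with equal cell counts per block and trial order
#' shuffled within each block. Ratings are left empty
#' ([simulate_agency_ratings()] fills them).
#'
#' @param trials_per_cell Trials per (delay, noise) cell (default 60, giving
#'   the standard 480-trial session).
#' @param n_blocks Number of blocks; `trials_per_cell` must be divisible by
#'   it (use `n_blocks = 1` for unblocked designs).
#' @param participant Participant identifier.
#' @param seed Optional integer seed; the same seed reproduces the table.
#' @return A tibble with columns `participant`, `block`, `trial`, `noise`,
#'   `delay_ms`, `joa` (NA), `rt_s` (NA), `error_flag` (FALSE).
#' @examples
#' generate_agency_design(seed = 1)
#' @export
generate_agency_design <- function(trials_per_cell = 60, n_blocks = 6,
                                   participant = "S01", seed = NULL) {
  if (trials_per_cell < 1) stop("`trials_per_cell` must be >= 1.",
                                call. = FALSE)
  if (trials_per_cell %% n_blocks != 0)
    stop("`trials_per_cell` must be divisible by `n_blocks` ",
         "(set `n_blocks = 1` for an unblocked design).", call. = FALSE)
  run <- function() {
    per_block <- trials_per_cell / n_blocks
    cells <- tidyr::expand_grid(delay_ms = c(0, 70, 100, 200),
                                noise = c("low", "high"))
    blocks <- purrr::map_dfr(seq_len(n_blocks), function(b) {
      block <- cells[rep(seq_len(nrow(cells)), each = per_block), ]
      block[sample.int(nrow(block)), c("noise", "delay_ms")] |>
        dplyr::mutate(block = b, .before = 1)
    })
    tibble::tibble(
      participant = participant,
      block = blocks$block,
      trial = seq_len(nrow(blocks)),
      noise = blocks$noise,
      delay_ms = blocks$delay_ms,
      joa = NA_integer_,
      rt_s = NA_real_,
      error_flag = FALSE
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fill a design with model-generated agency ratings
#'
#' Simulate a model-based observer on an agency design: per trial, draw an
#' internal signal from Normal(delay, sigma of the noise condition), classify
#' it by the model's rating criteria, and record the rating. Reaction times
#' are drawn uniformly from 0.3-3 s and no trial is flagged as an error;
#' these columns exist so that exclusion filters can be exercised, and carry
#' no physiological content.
#'
#' @param design A design table from [generate_agency_design()] (any table
#'   with `noise` and `delay_ms` columns works).
#' @param params A [model_params()] object with `n_yes` set.
#' @inheritParams place_criteria
#' @param seed Optional integer seed.
#' @return The design tibble with `joa`, `rt_s`, `error_flag` filled.
#' @export
simulate_agency_ratings <- function(design, params, d_max = 0.2,
                                    placement = c("per_side", "shared_max"),
                                    seed = NULL) {
  placement <- match.arg(placement)
  stopifnot(is.data.frame(design))
  check_noise(design$noise)
  run <- function() {
    sg <- sigma_for(params, design$noise)
    x <- stats::rnorm(nrow(design), mean = design$delay_ms / 1000, sd = sg)
    joa_sim <- integer(nrow(design))
    for (nz in unique(design$noise)) {
      g <- gamma_agency(params, sigma_for(params, nz), d_max, placement)
      sel <- design$noise == nz
      bin <- findInterval(x[sel], g[2:6]) + 1L
      joa_sim[sel] <- 7L - bin
    }
    dplyr::mutate(design,
                  joa = joa_sim,
                  rt_s = stats::runif(dplyr::n(), 0.3, 3),
                  error_flag = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a complete agency-rating session
#'
#' Convenience wrapper: [generate_agency_design()] then
#' [simulate_agency_ratings()] under a single seed.
#'
#' @inheritParams generate_agency_design
#' @inheritParams simulate_agency_ratings
#' @return A filled agency trial tibble.
#' @examples
#' simulate_agency_session(representative_params("first_order"), seed = 1)
#' @export
simulate_agency_session <- function(params, trials_per_cell = 60,
                                    n_blocks = 6, participant = "S01",
                                    d_max = 0.2,
                                    placement = c("per_side", "shared_max"),
                                    seed = NULL) {
  placement <- match.arg(placement)
  run <- function() {
    design <- generate_agency_design(trials_per_cell, n_blocks, participant)
    simulate_agency_ratings(design, params, d_max, placement)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Staircase settings for the 2IFC task
#'
#' Parameters of the 2-down-1-up adaptive staircase controlling the delay of
#' the delayed interval: the delay decreases by one step after two
#' consecutive correct responses and increases by one step after every
#' error, floored at `min_ms`. This rule converges on the delay yielding
#' about 70.7% correct. Defaults: start 300 ms, step 16.7 ms (one frame at a
#' 60 Hz display), floor one frame.
#'
#' @param start_ms Starting delay, ms.
#' @param step_ms Step size, ms.
#' @param min_ms Smallest allowed delay, ms.
#' @return A `staircase_config` list.
#' @export
staircase_config <- function(start_ms = 300, step_ms = 16.7, min_ms = 16.7) {
  if (!(start_ms > min_ms && min_ms > 0 && step_ms > 0))
    stop("Need start_ms > min_ms > 0 and step_ms > 0.", call. = FALSE)
  structure(list(start_ms = start_ms, step_ms = step_ms, min_ms = min_ms),
            class = "staircase_config")
}

#' Simulate a 2IFC confidence session
#'
#' Simulate a model-based observer on the two-interval forced-choice
#' confidence task. On each trial one interval carries a delay and the other
#' none; the observer's difference signal is Normal(delta, sigma), the
#' response is the interval perceived to have more agency, and confidence is
#' read off the 12-bin criteria of the model. Only the low-noise condition is
#' staircased (2-down-1-up on the delay); each high-noise trial reuses
#' (yokes) the delay of the low-noise trial with the same `staircase_trial`
#' index. The delayed interval is counterbalanced within each condition and
#' trial order is shuffled within blocks.
#'
#' @param params A [model_params()] object (`n_yes` ignored).
#' @param n_per_noise Trials per noise condition (default 100, giving the
#'   standard 200-trial session).
#' @param n_blocks Number of blocks; `n_per_noise` must be divisible by it.
#' @param staircase A [staircase_config()].
#' @param delta_max First-order scale anchor, seconds; defaults to the
#'   staircase start delay. Ignored by the Second-order model.
#' @param participant Participant identifier.
#' @param seed Optional integer seed.
#' @return A tibble with columns `participant`, `block`, `trial`, `noise`,
#'   `staircase_trial` (position in the staircased sequence; shared between a
#'   low-noise trial and its yoked high-noise trial), `delayed_interval`,
#'   `delay_ms`, `response_interval`, `confidence`, `correct`, `rt_s`,
#'   `error_flag`.
#' @examples
#' simulate_confidence_session(representative_params("second_order"),
#'                             seed = 1)
#' @export
simulate_confidence_session <- function(params, n_per_noise = 100,
                                        n_blocks = 5,
                                        staircase = staircase_config(),
                                        delta_max = NULL,
                                        participant = "S01", seed = NULL) {
  stopifnot(inherits(staircase, "staircase_config"))
  if (n_per_noise < 1) stop("`n_per_noise` must be >= 1.", call. = FALSE)
  if (n_per_noise %% n_blocks != 0)
    stop("`n_per_noise` must be divisible by `n_blocks`.", call. = FALSE)
  if (is.null(delta_max)) delta_max <- staircase$start_ms / 1000
  cc <- params$criterion
  run <- function() {
    # staircased low-noise delay sequence with online responses
    delay <- numeric(n_per_noise)
    d <- staircase$start_ms
    streak <- 0L
    delayed_lo <- sample(rep(1:2, length.out = n_per_noise))
    y_lo <- numeric(n_per_noise)
    for (i in seq_len(n_per_noise)) {
      delay[i] <- d
      delta <- if (delayed_lo[i] == 1L) d / 1000 else -d / 1000
      y_lo[i] <- stats::rnorm(1, delta, params$sigma_low)
      resp <- if (y_lo[i] > cc) 2L else 1L
      ok <- resp != delayed_lo[i]
      if (ok) {
        streak <- streak + 1L
        if (streak == 2L) {
          d <- max(d - staircase$step_ms, staircase$min_ms)
          streak <- 0L
        }
      } else {
        d <- d + staircase$step_ms
        streak <- 0L
      }
    }
    # yoked high-noise trials: same delay sequence, fresh signals
    delayed_hi <- sample(rep(1:2, length.out = n_per_noise))
    delta_hi <- ifelse(delayed_hi == 1L, delay, -delay) / 1000
    y_hi <- stats::rnorm(n_per_noise, delta_hi, params$sigma_high)

    one_noise <- function(nz, delayed, y) {
      g <- gamma_2ifc(params, sigma_for(params, nz), delta_max)
      bin <- findInterval(y, g[2:12]) + 1L
      resp <- ifelse(bin >= 7L, 2L, 1L)
      tibble::tibble(
        noise = nz,
        staircase_trial = seq_len(n_per_noise),
        delayed_interval = delayed,
        delay_ms = delay,
        response_interval = resp,
        confidence = as.integer(ifelse(bin >= 7L, bin - 6L, 7L - bin)),
        correct = resp != delayed
      )
    }
    out <- dplyr::bind_rows(one_noise("low", delayed_lo, y_lo),
                            one_noise("high", delayed_hi, y_hi))
    # assemble blocks: equal counts per condition per block, shuffled order
    per_block <- n_per_noise / n_blocks
    out$block <- rep(rep(seq_len(n_blocks), each = per_block), times = 2)
    out <- out[order(out$block, sample.int(nrow(out))), ]
    dplyr::mutate(out,
                  participant = participant,
                  trial = dplyr::row_number(),
                  rt_s = stats::runif(dplyr::n(), 0.3, 3),
                  error_flag = FALSE,
                  .before = 1) |>
      dplyr::select("participant", "block", "trial", "noise",
                    "staircase_trial", "delayed_interval", "delay_ms",
                    "response_interval", "confidence", "correct", "rt_s",
                    "error_flag")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Staircase accuracy after burn-in
#'
#' Proportion correct of the staircased (low-noise) trials of a simulated
#' 2IFC session after discarding the first `burn_in` staircase trials. With
#' a 2-down-1-up rule this converges to about 0.707 for long sessions.
#'
#' @param data A table from [simulate_confidence_session()].
#' @param burn_in Number of initial staircase trials to discard.
#' @return Proportion correct in `[0, 1]`.
#' @export
staircase_accuracy <- function(data, burn_in = 100) {
  stopifnot(all(c("noise", "staircase_trial", "correct") %in% names(data)))
  keep <- data$noise == "low" & data$staircase_trial > burn_in
  if (!any(keep)) stop("No staircase trials left after burn-in.",
                       call. = FALSE)
  mean(data$correct[keep])
}
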