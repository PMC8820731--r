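#' Second-order certainty of an agency decision
#'
#' Under the Second-order model the rating tracks the observer's certainty
#' that their Yes/No agency decision was correct given the internal signal
#' `x`: the posterior probability correct is `pnorm(abs(x - criterion) /
#' sigma)`, and certainty rescales it from the chance level 0.5 to the 0..1
#' range, `2 * pnorm(abs(x - criterion) / sigma) - 1`. Computing it requires
#' the observer to know their own sensory noise `sigma` -- the metacognitive
#' ingredient that distinguishes this model from the First-order one.
#'
#' @param x Internal signal(s), seconds (perceived delay; may be negative).
#' @param criterion Decision criterion, seconds.
#' @param sigma Internal-signal standard deviation, seconds (> 0).
#' @return Certainty value(s) in `[0, 1]`.
#' @examples
#' certainty_second_order(0.16, 0.16, 0.19)  # at the criterion: 0
#' certainty_second_order(0.35, 0.16, 0.19)  # one sigma away: ~0.683
#' @export
certainty_second_order <- function(x, criterion, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be positive.", call. = FALSE)
  2 * stats::pnorm(abs(x - criterion) / sigma) - 1
}

#' First-order evidence for an agency decision
#'
#' The First-order model rates agency proportionally to the signed distance
#' between a point estimate of the internal signal and the decision
#' criterion, `x - criterion`. Negative evidence (perceived delay below the
#' criterion) supports a "Yes, agency" decision. No estimate of the sensory
#' noise enters.
#'
#' @inheritParams certainty_second_order
#' @return Signed evidence, seconds.
#' @examples
#' evidence_first_order(0.26, 0.16)
#' @export
evidence_first_order <- function(x, criterion) {
  x - criterion
}

# ---- internal boundary construction ---------------------------------------
# All criteria are represented as the full ascending boundary vector
# gamma_1..gamma_{B+1} (first -Inf, last +Inf) delimiting B rating bins on
# the internal-signal axis. Bin k (left to right) maps to rating B+1-k:
# the lowest perceived delay gives the highest agency rating.

# 6-bin agency criteria; sigma is the spread of the relevant noise condition
gamma_agency <- function(params, sigma, d_max = 0.2,
                         placement = c("per_side", "shared_max")) {
  placement <- match.arg(placement)
  cc <- params$criterion
  m <- params$n_yes
  if (is.null(m)) stop("`n_yes` is required for 6-bin agency criteria.",
                       call. = FALSE)
  n_no <- 6L - m
  if (params$model == "second_order") {
    yes <- if (m > 1L) cc - sigma * stats::qnorm((1 + seq_len(m - 1L) / m) / 2)
    no  <- if (n_no > 1L)
      cc + sigma * stats::qnorm((1 + seq_len(n_no - 1L) / n_no) / 2)
  } else {
    s <- params$scale_range
    a_yes <- cc + s * sigma              # span from scale floor to criterion
    a_no  <- d_max + s * sigma - cc      # span from criterion to scale top
    if (a_yes <= 0 || a_no <= 0)
      stop("Criterion lies outside the First-order scale range.",
           call. = FALSE)
    if (placement == "shared_max") a_yes <- a_no <- max(a_yes, a_no)
    yes <- if (m > 1L) cc - seq_len(m - 1L) * a_yes / m
    no  <- if (n_no > 1L) cc + seq_len(n_no - 1L) * a_no / n_no
  }
  c(-Inf, sort(c(yes, cc, no)), Inf)
}

# 12-bin criteria on the 2IFC difference axis: six confidence levels on each
# side of the decision criterion
gamma_2ifc <- function(params, sigma, delta_max) {
  cc <- params$criterion
  if (params$model == "second_order") {
    off <- sigma * stats::qnorm((1 + seq_len(5L) / 6) / 2)
    lo <- cc - off
    hi <- cc + off
  } else {
    s <- params$scale_range
    half <- delta_max + s * sigma        # symmetric scale [-half, half]
    a_neg <- cc + half
    a_pos <- half - cc
    if (a_neg <= 0 || a_pos <= 0)
      stop("Criterion lies outside the First-order scale range.",
           call. = FALSE)
    lo <- cc - seq_len(5L) * a_neg / 6
    hi <- cc + seq_len(5L) * a_pos / 6
  }
  c(-Inf, sort(c(lo, cc, hi)), Inf)
}

#' Rating criteria on the internal-signal axis
#'
#' Compute, for each requested noise condition, the ordered boundaries that
#' carve the internal-signal axis into the six rating bins. Under the
#' Second-order model the boundaries sit at equal certainty levels on each
#' side of the decision criterion (so they move with the condition's noise);
#' under the First-order model they divide the per-condition scale range into
#' equal linear distances, the range being the most extreme programmed delay
#' padded by `scale_range` multiples of the condition's noise.
#'
#' `placement` chooses how the First-order per-side spans are formed:
#' `"per_side"` (default) divides the Yes-side and No-side spans separately,
#' mirroring the per-side binning of the Second-order model; `"shared_max"`
#' uses the larger of the two spans on both sides.
#'
#' @param params A [model_params()] object with `n_yes` set.
#' @param noise Character vector of noise conditions (`"low"`, `"high"`).
#' @param d_max Largest programmed delay, seconds (scale top for the
#'   First-order model).
#' @param placement First-order span rule, `"per_side"` or `"shared_max"`.
#' @return A tibble with columns `noise`, `boundary` (index 1..7; 1 and 7 are
#'   infinite), and `position_s`. Signals in bin `k` (between boundaries `k`
#'   and `k + 1`) receive rating `7 - k`.
#' @examples
#' place_criteria(representative_params("second_order"))
#' @export
place_criteria <- function(params, noise = c("low", "high"), d_max = 0.2,
                           placement = c("per_side", "shared_max")) {
  placement <- match.arg(placement)
  check_noise(noise)
  purrr::map_dfr(noise, function(nz) {
    g <- gamma_agency(params, sigma_for(params, nz), d_max, placement)
    tibble::tibble(noise = nz, boundary = seq_along(g), position_s = g)
  })
}

#' 2IFC confidence criteria on the difference axis
#'
#' The 12-bin variant of [place_criteria()] used for the two-interval
#' forced-choice confidence task: six confidence levels on each side of the
#' decision criterion on the signed delay-difference axis. The mapping
#' parameter is not used -- the task forces the assignment of ratings to
#' decisions.
#'
#' @param params A [model_params()] object (`n_yes` ignored).
#' @param noise Character vector of noise conditions.
#' @param delta_max Largest absolute delay difference realised in the data,
#'   seconds (sets the First-order scale range).
#' @return A tibble with columns `noise`, `boundary` (1..13), `position_s`.
#'   Bins 7..12 (above the criterion) are "interval 2 has more agency"
#'   responses with confidence 1..6; bins 6..1 mirror them for interval 1.
#' @export
place_criteria_2ifc <- function(params, noise = c("low", "high"),
                                delta_max = 0.3) {
  check_noise(noise)
  purrr::map_dfr(noise, function(nz) {
    g <- gamma_2ifc(params, sigma_for(params, nz), delta_max)
    tibble::tibble(noise = nz, boundary = seq_along(g), position_s = g)
  })
}
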