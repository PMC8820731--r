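#' Model parameter sets
#'
#' Bundle the parameters of a generative rating model. Both models share the
#' internal-signal spreads of the two sensory-noise conditions (`sigma_low`,
#' `sigma_high`, in seconds) and the decision criterion `criterion` (seconds)
#' separating "Yes, agency" decisions (perceived delay below the criterion)
#' from "No" decisions. For the 6-point agency scale, `n_yes` gives the number
#' of ratings mapped onto "Yes" decisions (the mapping parameter; 1-5). The
#' First-order model additionally carries `scale_range`, a positive multiplier
#' of the condition's noise that sets the bounds of the rating scale in signal
#' units.
#'
#' For the 2IFC confidence variant of the models `n_yes` is dropped (the task
#' forces six confidence ratings on each side of the decision criterion).
#'
#' @param model `"second_order"` or `"first_order"`.
#' @param sigma_low,sigma_high Internal-signal standard deviations (s) for the
#'   low- and high-noise conditions. Must be positive.
#' @param criterion Decision criterion on the internal-signal axis (s).
#' @param n_yes Integer in 1..5: number of ratings used for "Yes, agency"
#'   decisions, or `NULL` for the 2IFC confidence variant.
#' @param scale_range Positive scale-range multiplier (First-order model
#'   only), or `NULL`.
#'
#' @return An object of class `joa_params` (a named list).
#' @examples
#' model_params("second_order", 0.19, 0.24, 0.16, n_yes = 3)
#' model_params("first_order", 0.16, 0.16, 0.16, n_yes = 3, scale_range = 1.11)
#' @export
model_params <- function(model = c("second_order", "first_order"),
                         sigma_low, sigma_high, criterion,
                         n_yes = NULL, scale_range = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(sigma_low), length(sigma_low) == 1L,
            is.numeric(sigma_high), length(sigma_high) == 1L,
            is.numeric(criterion), length(criterion) == 1L)
  if (!is.finite(sigma_low) || sigma_low <= 0)
    stop("`sigma_low` must be a positive number.", call. = FALSE)
  if (!is.finite(sigma_high) || sigma_high <= 0)
    stop("`sigma_high` must be a positive number.", call. = FALSE)
  if (!is.null(n_yes)) {
    if (length(n_yes) != 1L || !is.finite(n_yes) || n_yes != round(n_yes) ||
        n_yes < 1 || n_yes > 5)
      stop("`n_yes` must be a whole number between 1 and 5.", call. = FALSE)
    n_yes <- as.integer(n_yes)
  }
  if (model == "first_order") {
    if (is.null(scale_range) || !is.finite(scale_range) || scale_range < 0)
      stop("First-order model needs a non-negative `scale_range`.",
           call. = FALSE)
  } else if (!is.null(scale_range)) {
    stop("`scale_range` applies to the First-order model only.", call. = FALSE)
  }
  structure(
    list(model = model, sigma_low = sigma_low, sigma_high = sigma_high,
         criterion = criterion, n_yes = n_yes, scale_range = scale_range),
    class = "joa_params"
  )
}

#' @export
print.joa_params <- function(x, ...) {
  cat("<joa_params> ", x$model, "\n", sep = "")
  cat(sprintf("  sigma_low = %.4g s, sigma_high = %.4g s, criterion = %.4g s\n",
              x$sigma_low, x$sigma_high, x$criterion))
  if (!is.null(x$n_yes)) cat("  n_yes =", x$n_yes, "\n")
  if (!is.null(x$scale_range)) cat("  scale_range =", x$scale_range, "\n")
  invisible(x)
}

#' Representative parameter values
#'
#' Parameter sets in the middle of the range typically recovered when these
#' models are fit to empirical agency-rating sessions. They drive the
#' synthetic-data generators and the recovery harnesses by default.
#'
#' @param model `"second_order"` or `"first_order"`.
#' @return A `joa_params` object.
#' @examples
#' representative_params("second_order")
#' @export
representative_params <- function(model = c("second_order", "first_order")) {
  model <- match.arg(model)
  if (model == "second_order") {
    model_params("second_order", sigma_low = 0.19, sigma_high = 0.24,
                 criterion = 0.16, n_yes = 3L)
  } else {
    model_params("first_order", sigma_low = 0.16, sigma_high = 0.16,
                 criterion = 0.16, n_yes = 3L, scale_range = 1.11)
  }
}

# sigma for one condition; noise is "low" or "high" (vectorised)
sigma_for <- function(params, noise) {
  bad <- !noise %in% c("low", "high")
  if (any(bad)) stop("Unknown noise label: ", paste(unique(noise[bad]),
                     collapse = ", "), call. = FALSE)
  ifelse(noise == "high", params$sigma_high, params$sigma_low)
}

check_noise <- function(noise) {
  if (!all(noise %in% c("low", "high")))
    stop("`noise` must be \"low\" or \"high\".", call. = FALSE)
  invisible(noise)
}
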