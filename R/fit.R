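#' Bounds for maximum-likelihood search
#'
#' Box constraints for the continuous parameters, on their natural scale.
#' Defaults cover the range plausible for delay signals of at most a few
#' hundred milliseconds: spreads between 5 ms and 1 s, criterion between
#' -100 ms and 400 ms, scale-range multiplier between 0.01 and 10.
#'
#' @param sigma Length-2 range for `sigma_low` and `sigma_high`, seconds.
#' @param criterion Length-2 range for the decision criterion, seconds.
#' @param scale_range Length-2 range for the First-order multiplier.
#' @return A named list of ranges.
#' @export
fit_bounds <- function(sigma = c(0.005, 1), criterion = c(-0.1, 0.4),
                       scale_range = c(0.01, 10)) {
  stopifnot(sigma[1] > 0, diff(sigma) > 0, diff(criterion) > 0,
            scale_range[1] > 0, diff(scale_range) > 0)
  list(sigma = sigma, criterion = criterion, scale_range = scale_range)
}

# ---- aggregated data and fast objectives ----------------------------------

# agency table -> per-noise list of delays (s) and 6 x D rating-count matrix
agg_agency <- function(data) {
  lapply(stats::setNames(nm = unique(data$noise)), function(nz) {
    sub <- data[data$noise == nz, ]
    delays <- sort(unique(sub$delay_ms)) / 1000
    counts <- unclass(table(factor(sub$joa, levels = 1:6),
                            factor(sub$delay_ms / 1000, levels = delays)))
    list(delays = delays, counts = counts)
  })
}

# confidence table -> per-noise deltas (s) and 12 x D bin-count matrix
agg_2ifc <- function(data) {
  delta <- delta_2ifc(data)
  bin <- bin_index_2ifc(data$response_interval, data$confidence)
  out <- lapply(stats::setNames(nm = unique(data$noise)), function(nz) {
    sel <- data$noise == nz
    deltas <- sort(unique(delta[sel]))
    counts <- unclass(table(factor(bin[sel], levels = 1:12),
                            factor(delta[sel], levels = deltas)))
    list(deltas = deltas, counts = counts)
  })
  attr(out, "delta_max") <- max(abs(delta))
  out
}

BIG <- 1e10

# negative log-likelihood closures over aggregated counts; theta holds
# log(sigma_low), log(sigma_high), criterion[, log(scale_range)]
make_nll_agency <- function(agg, model, n_yes, d_max, placement, bounds,
                            prob_floor) {
  first <- model == "first_order"
  function(theta) {
    sl <- exp(theta[1]); sh <- exp(theta[2]); cc <- theta[3]
    s <- if (first) exp(theta[4]) else NULL
    if (sl < bounds$sigma[1] || sl > bounds$sigma[2] ||
        sh < bounds$sigma[1] || sh > bounds$sigma[2] ||
        cc < bounds$criterion[1] || cc > bounds$criterion[2]) return(BIG)
    if (first && (s < bounds$scale_range[1] || s > bounds$scale_range[2]))
      return(BIG)
    p <- list(model = model, criterion = cc, n_yes = n_yes, scale_range = s)
    ll <- 0
    for (nz in names(agg)) {
      sg <- if (nz == "high") sh else sl
      if (first && (cc + s * sg <= 0 || d_max + s * sg - cc <= 0))
        return(BIG)
      g <- gamma_agency(p, sg, d_max, placement)
      pm <- bin_prob_matrix(g, agg[[nz]]$delays, sg)[6:1, , drop = FALSE]
      ll <- ll + sum(agg[[nz]]$counts * log(pmax(pm, prob_floor)))
    }
    if (!is.finite(ll)) return(BIG)
    -ll
  }
}

make_nll_2ifc <- function(agg, model, delta_max, bounds, prob_floor) {
  first <- model == "first_order"
  function(theta) {
    sl <- exp(theta[1]); sh <- exp(theta[2]); cc <- theta[3]
    s <- if (first) exp(theta[4]) else NULL
    if (sl < bounds$sigma[1] || sl > bounds$sigma[2] ||
        sh < bounds$sigma[1] || sh > bounds$sigma[2] ||
        cc < bounds$criterion[1] || cc > bounds$criterion[2]) return(BIG)
    if (first && (s < bounds$scale_range[1] || s > bounds$scale_range[2]))
      return(BIG)
    p <- list(model = model, criterion = cc, scale_range = s)
    ll <- 0
    for (nz in names(agg)) {
      sg <- if (nz == "high") sh else sl
      if (first && (cc + delta_max + s * sg <= 0 ||
                    delta_max + s * sg - cc <= 0)) return(BIG)
      g <- gamma_2ifc(p, sg, delta_max)
      pm <- bin_prob_matrix(g, agg[[nz]]$deltas, sg)
      ll <- ll + sum(agg[[nz]]$counts * log(pmax(pm, prob_floor)))
    }
    if (!is.finite(ll)) return(BIG)
    -ll
  }
}

# Latin-hypercube start points in theta space
lhs_starts <- function(n_starts, bounds, first_order) {
  dim <- if (first_order) 4L else 3L
  u <- lhs::randomLHS(n_starts, dim)
  lo <- c(log(bounds$sigma[1]), log(bounds$sigma[1]), bounds$criterion[1],
          log(bounds$scale_range[1]))[seq_len(dim)]
  hi <- c(log(bounds$sigma[2]), log(bounds$sigma[2]), bounds$criterion[2],
          log(bounds$scale_range[2]))[seq_len(dim)]
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

multistart <- function(nll, starts, control) {
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], nll, method = "Nelder-Mead",
                        control = control)
    if (fit$convergence == 0L && fit$value < BIG) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$n_conv <- n_conv
  best
}

#' Maximum-likelihood fit of a rating model
#'
#' Fit either generative model to an agency-rating table or a 2IFC
#' confidence table by maximum likelihood. Continuous parameters
#' (`sigma_low`, `sigma_high`, `criterion`, and `scale_range` for the
#' First-order model) are optimised by multistart Nelder-Mead simplex search
#' from Latin-hypercube start points inside [fit_bounds()]; spreads and the
#' scale range are searched on the log scale. For the agency task the
#' discrete mapping parameter `n_yes` is enumerated exhaustively over 1..5
#' and the best combination returned; the confidence task has no mapping
#' parameter (six ratings per side are forced).
#'
#' The parameter count `k` entering AIC and BIC includes `n_yes` where it is
#' fit: 4 (Second-order) and 5 (First-order) on the agency task, 3 and 4 on
#' the confidence task.
#'
#' @param data An agency trial table (columns `noise`, `delay_ms`, `joa`) or
#'   confidence table (columns `noise`, `delayed_interval`, `delay_ms`,
#'   `response_interval`, `confidence`), typically pre-filtered with
#'   [filter_trials()]. Pooled group fits are obtained by passing several
#'   participants' rows at once.
#' @param model `"second_order"` or `"first_order"`.
#' @param task `"agency"` or `"confidence"`.
#' @param n_starts Number of Nelder-Mead starts per `n_yes` value.
#' @param seed Optional integer seed controlling the start points.
#' @param bounds Box constraints from [fit_bounds()].
#' @inheritParams loglik_agency
#' @param reltol Relative convergence tolerance passed to the optimiser.
#' @param maxit Maximum simplex iterations per start.
#' @return A `joa_fit` object: fitted [model_params()], `logLik`, `AIC`,
#'   `BIC`, trial count `n`, parameter count `k`, and convergence
#'   diagnostics. [tidy()] and [glance()] methods are provided.
#' @examples
#' dat <- simulate_agency_session(representative_params("second_order"),
#'                                trials_per_cell = 30, seed = 1)
#' fit <- fit_model(dat, "second_order", "agency", n_starts = 5, seed = 1)
#' glance(fit)
#' @export
fit_model <- function(data, model = c("second_order", "first_order"),
                      task = c("agency", "confidence"), n_starts = 20,
                      seed = NULL, bounds = fit_bounds(), d_max = 0.2,
                      placement = c("per_side", "shared_max"),
                      prob_floor = 1e-300, reltol = 1e-8, maxit = 1000) {
  model <- match.arg(model)
  task <- match.arg(task)
  placement <- match.arg(placement)
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("Empty trial table.", call. = FALSE)
  check_noise(data$noise)
  if (length(unique(data$noise)) < 2)
    stop("Need trials from both noise conditions.", call. = FALSE)
  first <- model == "first_order"
  control <- list(reltol = reltol, maxit = maxit)
  rating_col <- if (task == "agency") data$joa else data$confidence
  degenerate <- length(unique(rating_col)) == 1L
  if (degenerate)
    warning("All trials carry the same rating; the fit is weakly ",
            "identified and may sit on a bound.", call. = FALSE)
  run <- function() {
    if (task == "agency") {
      agg <- agg_agency(data)
      best <- NULL
      for (ny in 1:5) {
        nll <- make_nll_agency(agg, model, ny, d_max, placement, bounds,
                               prob_floor)
        res <- multistart(nll, lhs_starts(n_starts, bounds, first), control)
        res$n_yes <- ny
        if (is.null(best) || res$value < best$value) best <- res
      }
      best
    } else {
      agg <- agg_2ifc(data)
      nll <- make_nll_2ifc(agg, model, attr(agg, "delta_max"), bounds,
                           prob_floor)
      res <- multistart(nll, lhs_starts(n_starts, bounds, first), control)
      res$delta_max <- attr(agg, "delta_max")
      res
    }
  }
  best <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (best$value >= BIG)
    stop("No start converged to a valid parameter set; widen `bounds` or ",
         "increase `n_starts`.", call. = FALSE)
  th <- best$par
  params <- model_params(
    model, sigma_low = exp(th[1]), sigma_high = exp(th[2]), criterion = th[3],
    n_yes = if (task == "agency") best$n_yes else NULL,
    scale_range = if (first) exp(th[4]) else NULL
  )
  n <- nrow(data)
  k <- if (task == "agency") 3L + first + 1L else 3L + first
  ll <- -best$value
  structure(
    list(model = model, task = task, params = params, logLik = ll,
         n = n, k = as.integer(k), aic = 2 * k - 2 * ll,
         bic = k * log(n) - 2 * ll, n_starts = n_starts,
         n_starts_converged = best$n_conv, seed = seed,
         d_max = d_max, placement = placement,
         delta_max = best$delta_max, degenerate = degenerate),
    class = "joa_fit"
  )
}

#' @export
print.joa_fit <- function(x, ...) {
  cat("<joa_fit> ", x$model, " / ", x$task, " task\n", sep = "")
  print(x$params)
  cat(sprintf("  logLik = %.2f, AIC = %.2f, BIC = %.2f (k = %d, n = %d)\n",
              x$logLik, x$aic, x$bic, x$k, x$n))
  cat(sprintf("  %d/%d starts converged\n", x$n_starts_converged,
              x$n_starts))
  invisible(x)
}

#' @export
logLik.joa_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @rdname fit_model
#' @param x A `joa_fit` object.
#' @param ... Unused.
#' @method tidy joa_fit
#' @export
tidy.joa_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("sigma_low", "sigma_high", "criterion",
             if (!is.null(p$n_yes)) "n_yes",
             if (!is.null(p$scale_range)) "scale_range"),
    estimate = c(p$sigma_low, p$sigma_high, p$criterion,
                 if (!is.null(p$n_yes)) p$n_yes,
                 if (!is.null(p$scale_range)) p$scale_range)
  )
}

#' @rdname fit_model
#' @method glance joa_fit
#' @export
glance.joa_fit <- function(x, ...) {
  tibble::tibble(model = x$model, task = x$task, logLik = x$logLik,
                 AIC = x$aic, BIC = x$bic, k = x$k, n = x$n,
                 n_starts_converged = x$n_starts_converged)
}

#' Fit both models to each participant
#'
#' Convenience wrapper running [fit_model()] for every participant and both
#' models, returning one row per (participant, model) with the fit summary
#' and estimates. The `AIC` column feeds directly into [rfx_bms()] via
#' `log_evidence = -AIC / 2`.
#'
#' @inheritParams fit_model
#' @param models Character vector of models to fit.
#' @return A tibble with columns `participant`, `model`, `logLik`, `AIC`,
#'   `BIC`, `k`, `n`, and the parameter estimates.
#' @export
fit_by_participant <- function(data, models = c("second_order",
                                                "first_order"),
                               task = c("agency", "confidence"),
                               n_starts = 20, seed = NULL, ...) {
  task <- match.arg(task)
  stopifnot("participant" %in% names(data))
  grid <- tidyr::expand_grid(participant = unique(data$participant),
                             model = models)
  purrr::pmap_dfr(grid, function(participant, model) {
    fit <- fit_model(data[data$participant == participant, ], model, task,
                     n_starts = n_starts, seed = seed, ...)
    est <- tidy(fit)
    dplyr::bind_cols(
      tibble::tibble(participant = participant),
      glance(fit)[c("model", "logLik", "AIC", "BIC", "k", "n")],
      tidyr::pivot_wider(est, names_from = "term", values_from = "estimate")
    )
  })
}
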