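default_param_sets <- function() {
  list(second_order = list(representative_params("second_order")),
       first_order = list(representative_params("first_order")))
}

#' Model recovery
#'
#' Closes the simulate-fit-select loop: for each generating model, simulate
#' agency sessions at the supplied parameter sets, fit both models to each
#' simulated session, and record which model wins by BIC. A confusion matrix
#' concentrated on the diagonal shows that the two models are distinguishable
#' at the simulated session size.
#'
#' @param param_sets Named list with elements `second_order` and
#'   `first_order`, each a list of [model_params()] objects cycled over
#'   simulations. Defaults to [representative_params()] for each model.
#' @param n_sims Simulated sessions per generating model.
#' @param trials_per_cell Trials per (delay, noise) cell per session
#'   (60 gives the standard 480-trial session). Sessions are simulated
#'   unblocked.
#' @param seed Optional integer seed controlling simulations and fits.
#' @param n_starts Optimiser starts per fit (recovery default 5; the
#'   likelihood surfaces here are smooth and low-dimensional).
#' @param ... Further arguments passed to [fit_model()].
#' @return A `joa_recovery` object whose `confusion` element is a tibble of
#'   (generating, winner) counts; `results` holds one row per simulation.
#'   Failed fits are logged and skipped.
#' @export
model_recovery <- function(param_sets = default_param_sets(), n_sims = 100,
                           trials_per_cell = 60, seed = NULL, n_starts = 5,
                           ...) {
  if (n_sims < 1) stop("`n_sims` must be >= 1.", call. = FALSE)
  stopifnot(all(c("second_order", "first_order") %in% names(param_sets)))
  run <- function() {
    purrr::map_dfr(c("second_order", "first_order"), function(gen) {
      sets <- param_sets[[gen]]
      purrr::map_dfr(seq_len(n_sims), function(i) {
        truth <- sets[[(i - 1L) %% length(sets) + 1L]]
        dat <- simulate_agency_session(truth, trials_per_cell,
                                       n_blocks = 1)
        res <- tryCatch({
          f2 <- fit_model(dat, "second_order", "agency",
                          n_starts = n_starts, ...)
          f1 <- fit_model(dat, "first_order", "agency",
                          n_starts = n_starts, ...)
          tibble::tibble(generating = gen, sim = i,
                         bic_second = f2$bic, bic_first = f1$bic,
                         winner = ifelse(f2$bic < f1$bic, "second_order",
                                         "first_order"),
                         failed = FALSE)
        }, error = function(e) {
          tibble::tibble(generating = gen, sim = i, bic_second = NA_real_,
                         bic_first = NA_real_, winner = NA_character_,
                         failed = TRUE)
        })
        res
      })
    })
  }
  results <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  confusion <- results |>
    dplyr::filter(!.data$failed) |>
    dplyr::count(.data$generating, .data$winner, name = "n") |>
    tidyr::complete(generating = c("second_order", "first_order"),
                    winner = c("second_order", "first_order"),
                    fill = list(n = 0L))
  structure(
    list(type = "model", confusion = confusion, results = results,
         settings = list(n_sims = n_sims, trials_per_cell = trials_per_cell,
                         n_starts = n_starts, seed = seed),
         n_failed = sum(results$failed)),
    class = "joa_recovery"
  )
}

#' Parameter recovery
#'
#' Simulate sessions from known parameters, refit the generating model, and
#' summarise per-parameter bias and root-mean-square error, plus the hit
#' rate of the discrete mapping parameter. Shrinking bias and RMSE with
#' growing session size is the expected signature of a consistent estimator.
#'
#' @param params True [model_params()] generating the sessions.
#' @param n_sims Number of simulated sessions.
#' @inheritParams model_recovery
#' @return A `joa_recovery` object with `estimates` (one row per simulation
#'   and parameter) and `bias_rmse` (per-parameter truth, bias, RMSE, and
#'   for `n_yes` the exact-recovery rate).
#' @export
parameter_recovery <- function(params, n_sims = 20, trials_per_cell = 60,
                               seed = NULL, n_starts = 5, ...) {
  if (n_sims < 1) stop("`n_sims` must be >= 1.", call. = FALSE)
  stopifnot(inherits(params, "joa_params"))
  run <- function() {
    purrr::map_dfr(seq_len(n_sims), function(i) {
      dat <- simulate_agency_session(params, trials_per_cell, n_blocks = 1)
      res <- tryCatch({
        fit <- fit_model(dat, params$model, "agency", n_starts = n_starts,
                         ...)
        dplyr::mutate(tidy(fit), sim = i, failed = FALSE)
      }, error = function(e) {
        tibble::tibble(term = NA_character_, estimate = NA_real_, sim = i,
                       failed = TRUE)
      })
      res
    })
  }
  estimates <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  truth <- tidy_params(params)
  bias_rmse <- estimates |>
    dplyr::filter(!.data$failed) |>
    dplyr::inner_join(truth, by = "term") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      truth = .data$true[1],
      bias = mean(.data$estimate - .data$true),
      rmse = sqrt(mean((.data$estimate - .data$true)^2)),
      exact_rate = mean(.data$estimate == .data$true),
      .groups = "drop"
    )
  structure(
    list(type = "parameter", estimates = estimates, bias_rmse = bias_rmse,
         truth = params,
         settings = list(n_sims = n_sims, trials_per_cell = trials_per_cell,
                         n_starts = n_starts, seed = seed),
         n_failed = sum(estimates$failed[!duplicated(estimates$sim)])),
    class = "joa_recovery"
  )
}

tidy_params <- function(params) {
  tibble::tibble(
    term = c("sigma_low", "sigma_high", "criterion",
             if (!is.null(params$n_yes)) "n_yes",
             if (!is.null(params$scale_range)) "scale_range"),
    true = c(params$sigma_low, params$sigma_high, params$criterion,
             if (!is.null(params$n_yes)) params$n_yes,
             if (!is.null(params$scale_range)) params$scale_range)
  )
}

#' @export
print.joa_recovery <- function(x, ...) {
  cat("<joa_recovery> ", x$type, " recovery, ", x$settings$n_sims,
      " simulations of ", x$settings$trials_per_cell * 8,
      " trials each\n", sep = "")
  if (x$type == "model") print(x$confusion) else print(x$bias_rmse)
  if (x$n_failed > 0) cat(x$n_failed, "simulation(s) failed and were",
                          "skipped.\n")
  invisible(x)
}

#' @rdname model_recovery
#' @param x A `joa_recovery` object.
#' @param ... Unused.
#' @method tidy joa_recovery
#' @export
tidy.joa_recovery <- function(x, ...) {
  if (x$type == "model") x$confusion else x$bias_rmse
}

#' Diagonal proportion of a model-recovery confusion matrix
#'
#' @param x A `joa_recovery` object from [model_recovery()].
#' @return A tibble with one row per generating model and the proportion of
#'   simulations in which the generating model won by BIC.
#' @export
recovery_rate <- function(x) {
  stopifnot(inherits(x, "joa_recovery"), x$type == "model")
  x$confusion |>
    dplyr::group_by(.data$generating) |>
    dplyr::summarise(
      rate = sum(.data$n[.data$winner == .data$generating]) / sum(.data$n),
      .groups = "drop"
    )
}
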