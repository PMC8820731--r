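agency_cols <- c("participant", "block", "trial", "noise", "delay_ms",
                 "joa", "rt_s", "error_flag")
confidence_cols <- c("participant", "block", "trial", "noise",
                     "delayed_interval", "delay_ms", "response_interval",
                     "confidence", "rt_s", "error_flag")

validate_trials <- function(data, task) {
  need <- if (task == "agency") agency_cols else confidence_cols
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("Missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_noise <- which(!data$noise %in% c("low", "high"))
  if (length(bad_noise) > 0)
    stop("Unknown noise label in row(s): ",
         paste(utils::head(bad_noise, 10), collapse = ", "), call. = FALSE)
  rating <- if (task == "agency") data$joa else data$confidence
  bad <- which(!is.na(rating) & !(rating %in% 1:6))
  if (length(bad) > 0)
    stop("Rating outside 1..6 in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if (task == "confidence") {
    bad_d <- which(data$delay_ms <= 0)
    if (length(bad_d) > 0)
      stop("Non-positive staircased delay in row(s): ",
           paste(utils::head(bad_d, 10), collapse = ", "), call. = FALSE)
    bad_i <- which(!data$delayed_interval %in% 1:2 |
                     !data$response_interval %in% 1:2)
    if (length(bad_i) > 0)
      stop("Interval outside {1, 2} in row(s): ",
           paste(utils::head(bad_i, 10), collapse = ", "), call. = FALSE)
  }
  invisible(data)
}

#' Read and write trial tables
#'
#' CSV readers and writers for the two trial-table dialects. Files store
#' delays in milliseconds and reaction times in seconds; tables are kept in
#' those units in memory and model functions convert delays to seconds
#' internally. Unknown columns are preserved. `col_map` renames columns of a
#' foreign file into the expected dialect, e.g.
#' `c(joa = "rating", delay_ms = "lag")` (expected name = file name).
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping expected column
#'   names to the names used in the file.
#' @return `read_*` return a validated tibble; `write_*` return `path`
#'   invisibly.
#' @name trial_io
#' @export
read_agency_trials <- function(path, col_map = NULL) {
  read_trials(path, "agency", col_map)
}

#' @rdname trial_io
#' @export
read_confidence_trials <- function(path, col_map = NULL) {
  read_trials(path, "confidence", col_map)
}

read_trials <- function(path, task, col_map = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    found <- intersect(unname(col_map), names(data))
    map <- col_map[col_map %in% found]
    data <- dplyr::rename(data, !!!rlang::set_names(map, names(map)))
  }
  validate_trials(data, task)
  rating <- if (task == "agency") "joa" else "confidence"
  data[[rating]] <- as.integer(data[[rating]])
  data$error_flag <- as.logical(data$error_flag)
  data
}

#' @rdname trial_io
#' @param data A trial table.
#' @export
write_agency_trials <- function(data, path) {
  validate_trials(data, "agency")
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname trial_io
#' @export
write_confidence_trials <- function(data, path) {
  validate_trials(data, "confidence")
  readr::write_csv(data, path)
  invisible(path)
}

#' Exclude error and implausible-RT trials
#'
#' Standard pre-analysis filter: drop trials flagged as errors and trials
#' whose reaction time falls outside `[rt_min, rt_max]` (defaults 100 ms and
#' 8 s). The counts removed per reason are attached as the `"exclusions"`
#' attribute, retrievable with [exclusion_log()].
#'
#' @param data A trial table with `rt_s` and `error_flag` columns.
#' @param rt_min,rt_max Reaction-time bounds, seconds.
#' @return The filtered tibble.
#' @export
filter_trials <- function(data, rt_min = 0.1, rt_max = 8) {
  stopifnot(all(c("rt_s", "error_flag") %in% names(data)),
            rt_min > 0, rt_max > rt_min)
  err <- data$error_flag
  fast <- !err & data$rt_s < rt_min
  slow <- !err & data$rt_s > rt_max
  out <- data[!(err | fast | slow), ]
  attr(out, "exclusions") <- tibble::tibble(
    reason = c("error_flag", "rt_too_fast", "rt_too_slow"),
    n = c(sum(err), sum(fast), sum(slow))
  )
  out
}

#' @rdname filter_trials
#' @param x A table returned by [filter_trials()].
#' @export
exclusion_log <- function(x) {
  log <- attr(x, "exclusions")
  if (is.null(log)) stop("No exclusion log attached.", call. = FALSE)
  log
}

#' Per-condition rating means
#'
#' Mean agency rating and trial count for every (noise, delay) cell of the
#' design. Cells absent from the data appear with `NA` mean and zero count.
#'
#' @param data An agency trial table with filled `joa`.
#' @return A tibble with columns `noise`, `delay_ms`, `mean_joa`, `n`.
#' @export
summarize_behavior <- function(data) {
  stopifnot(all(c("noise", "delay_ms", "joa") %in% names(data)))
  data |>
    dplyr::group_by(.data$noise, .data$delay_ms) |>
    dplyr::summarise(mean_joa = mean(.data$joa), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::complete(noise = c("low", "high"),
                    delay_ms = unique(data$delay_ms),
                    fill = list(n = 0L)) |>
    dplyr::arrange(.data$noise, .data$delay_ms)
}

#' Delay slope of mean ratings per noise condition
#'
#' Ordinary least-squares slope of the per-cell mean rating on the true
#' delay, separately per noise condition. Units are rating points per second
#' of delay -- a descriptive summary of how steeply agency falls with delay
#' (model-based observers with second-order noise monitoring, or first-order
#' rescaling, both flatten the high-noise slope). Not comparable to
#' mixed-effects regression coefficients on other delay scalings.
#'
#' @inheritParams summarize_behavior
#' @return A tibble with columns `noise`, `slope` (rating / s), `intercept`.
#' @export
delay_slopes <- function(data) {
  summarize_behavior(data) |>
    dplyr::filter(!is.na(.data$mean_joa)) |>
    dplyr::group_by(.data$noise) |>
    dplyr::summarise(
      slope = stats::coef(stats::lm(mean_joa ~ I(delay_ms / 1000)))[[2]],
      intercept = stats::coef(stats::lm(mean_joa ~ I(delay_ms / 1000)))[[1]],
      .groups = "drop"
    )
}
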