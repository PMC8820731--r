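test_that("rating probabilities normalise and respect limits", {
  grid <- expand.grid(model = c("second_order", "first_order"),
                      ny = c(1, 3, 5), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    p <- model_params(grid$model[i], 0.19, 0.24, 0.16, n_yes = grid$ny[i],
                      scale_range = if (grid$model[i] == "first_order") 1.11)
    probs <- rating_probabilities(p, c(0, 0.07, 0.1, 0.2))
    sums <- tapply(probs$prob, list(probs$delay_s, probs$noise), sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(probs$prob >= 0))
  }
  # a huge delay pushes all mass into the lowest rating
  p <- representative_params("second_order")
  far <- rating_probabilities(p, 10, "low")
  expect_gt(far$prob[far$rating == 1], 1 - 1e-12)
})

test_that("closed-form probabilities match a Monte-Carlo signal-classification oracle", {
  p <- representative_params("second_order")
  n <- 2e5
  withr::with_seed(42, {
    x <- rnorm(n, 0, p$sigma_low)
  })
  # oracle: classify raw Normal draws by the criteria and compare the
  # resulting frequencies to the closed-form CDF differences
  bin <- findInterval(x, interior(p, "low")) + 1L
  emp <- tabulate(7L - bin, 6L) / n
  want <- rating_probabilities(p, 0, "low")
  want <- want$prob[order(want$rating)]
  se <- sqrt(want * (1 - want) / n)
  expect_true(all(abs(emp - want) < 3.5 * se))
  expect_equal(want[6], 0.45, tolerance = 0.01)  # high agency at zero delay
})

test_that("raising the spread pulls second-order ratings toward mid-scale", {
  d <- 0.1
  extremeness <- vapply(c(0.1, 0.2, 0.3), function(sg) {
    p <- model_params("second_order", sg, sg, 0.16, n_yes = 3)
    probs <- rating_probabilities(p, d, "low")
    sum(probs$prob * abs(probs$rating - 3.5))
  }, numeric(1))
  expect_true(all(diff(extremeness) < 0))
})

test_that("expected rating is non-increasing in delay for both models", {
  delays <- seq(0, 0.2, by = 0.02)
  for (p in list(representative_params("second_order"),
                 representative_params("first_order"))) {
    for (nz in c("low", "high")) {
      m <- rating_probabilities(p, delays, nz) |>
        dplyr::group_by(delay_s) |>
        dplyr::summarise(er = sum(rating * prob))
      expect_true(all(diff(m$er) <= 1e-12))
    }
  }
})

test_that("agency log-likelihood scores single trials and adds over tables", {
  p <- representative_params("second_order")
  one <- tibble::tibble(noise = "low", delay_ms = 100, joa = 4L)
  probs <- rating_probabilities(p, 0.1, "low")
  expect_equal(loglik_agency(one, p), log(probs$prob[probs$rating == 4]))
  a <- simulate_agency_session(p, trials_per_cell = 10, n_blocks = 1,
                               seed = 1)
  b <- simulate_agency_session(p, trials_per_cell = 10, n_blocks = 1,
                               seed = 2)
  expect_equal(loglik_agency(dplyr::bind_rows(a, b), p),
               loglik_agency(a, p) + loglik_agency(b, p))
})

test_that("per-trial mean log-likelihood matches the analytic entropy oracle", {
  p <- representative_params("second_order")
  n_cell <- 12500  # 1e5 trials over the 8 design cells
  dat <- simulate_agency_session(p, trials_per_cell = n_cell, n_blocks = 1,
                                 seed = 3)
  got <- loglik_agency(dat, p) / nrow(dat)
  probs <- rating_probabilities(p, c(0, 0.07, 0.1, 0.2))
  want <- mean(tapply(probs$prob, list(probs$delay_s, probs$noise),
                      function(q) sum(q * log(q))))
  # Monte-Carlo error of the mean of log p at this n is ~0.003
  expect_equal(got, want, tolerance = 0.01)
})

test_that("agency log-likelihood rejects malformed tables", {
  p <- representative_params("second_order")
  expect_error(loglik_agency(tibble::tibble(noise = character(),
                                            delay_ms = numeric(),
                                            joa = integer()), p), "Empty")
  expect_error(loglik_agency(tibble::tibble(noise = "dusk", delay_ms = 0,
                                            joa = 3L), p), "noise")
  expect_error(loglik_agency(tibble::tibble(noise = "low", delay_ms = 0,
                                            joa = 9L), p), "1..6")
})
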