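test_that("the agency design has the right cell structure", {
  d <- generate_agency_design(trials_per_cell = 60, seed = 1)
  expect_equal(nrow(d), 480L)
  expect_equal(mean(d$delay_ms == 0), 0.25)
  cells <- dplyr::count(d, noise, delay_ms)
  expect_true(all(cells$n == 60))
  # equal cell counts within every block
  per_block <- dplyr::count(d, block, noise, delay_ms)
  expect_true(all(per_block$n == 10))
  expect_error(generate_agency_design(trials_per_cell = 7, n_blocks = 6),
               "divisible")
})

test_that("generators are seed-deterministic and seed-sensitive", {
  expect_identical(generate_agency_design(seed = 5),
                   generate_agency_design(seed = 5))
  expect_false(identical(generate_agency_design(seed = 5)$delay_ms,
                         generate_agency_design(seed = 6)$delay_ms))
  s1 <- simulate_confidence_session(p_second, seed = 5)
  expect_identical(s1, simulate_confidence_session(p_second, seed = 5))
  a1 <- simulate_agency_session(p_first, trials_per_cell = 12, seed = 5)
  expect_identical(a1, simulate_agency_session(p_first, trials_per_cell = 12,
                                               seed = 5))
})

test_that("simulated ratings follow the closed-form distribution", {
  n <- 1e5
  des <- flat_design(n, delay_ms = 70, noise = "high")
  sim <- simulate_agency_ratings(des, p_second, seed = 11)
  expect_true(all(sim$joa %in% 1:6))
  emp <- tabulate(sim$joa, 6L) / n
  want <- rating_probabilities(p_second, 0.07, "high")
  want <- want$prob[order(want$rating)]
  se <- sqrt(want * (1 - want) / n)
  expect_true(all(abs(emp - want) < 3.5 * se))
})

test_that("a noiseless observer with sub-criterion delay always reports full agency", {
  p <- model_params("second_order", 1e-9, 1e-9, 0.16, n_yes = 3)
  sim <- simulate_agency_ratings(flat_design(200, 0, "low"), p, seed = 2)
  expect_true(all(sim$joa == 6L))
})

test_that("the confidence session matches the task design", {
  s <- simulate_confidence_session(p_second, n_per_noise = 100, seed = 3)
  expect_equal(nrow(s), 200L)
  expect_equal(sum(s$noise == "low"), 100L)
  # yoking: the high-noise delay sequence equals the staircased low-noise one
  lo <- dplyr::arrange(dplyr::filter(s, noise == "low"), staircase_trial)
  hi <- dplyr::arrange(dplyr::filter(s, noise == "high"), staircase_trial)
  expect_identical(hi$delay_ms, lo$delay_ms)
  # delayed interval counterbalanced within condition
  expect_equal(sum(lo$delayed_interval == 1), 50L)
  # correctness flag consistent with intervals
  expect_identical(s$correct, s$response_interval != s$delayed_interval)
})

test_that("low-noise delays follow the 2-down-1-up rule (reference oracle)", {
  sc <- staircase_config(start_ms = 300, step_ms = 16.7, min_ms = 16.7)
  s <- simulate_confidence_session(p_second, n_per_noise = 200, n_blocks = 1,
                                   staircase = sc, seed = 13)
  lo <- dplyr::arrange(dplyr::filter(s, noise == "low"), staircase_trial)
  # reference reimplementation of the rule from the realised correctness
  d <- sc$start_ms
  streak <- 0L
  want <- numeric(nrow(lo))
  for (i in seq_len(nrow(lo))) {
    want[i] <- d
    if (lo$correct[i]) {
      streak <- streak + 1L
      if (streak == 2L) {
        d <- max(d - sc$step_ms, sc$min_ms)
        streak <- 0L
      }
    } else {
      d <- d + sc$step_ms
      streak <- 0L
    }
  }
  expect_equal(lo$delay_ms, want)
})

test_that("the staircase converges near the 2-down-1-up fixed point", {
  s <- simulate_confidence_session(p_second, n_per_noise = 2000,
                                   n_blocks = 1, seed = 17)
  acc <- staircase_accuracy(s, burn_in = 100)
  expect_equal(acc, 0.707, tolerance = 0.03)
})

test_that("noisier conditions flatten the mean-rating slope over delays", {
  dat <- simulate_agency_session(p_second, trials_per_cell = 500,
                                 n_blocks = 1, seed = 19)
  sl <- delay_slopes(dat)
  expect_lt(abs(sl$slope[sl$noise == "high"]),
            abs(sl$slope[sl$noise == "low"]))
  expect_true(all(sl$slope < 0))
})
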