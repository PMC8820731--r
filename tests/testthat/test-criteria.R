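test_that("second-order certainty behaves like a folded probability-correct", {
  expect_equal(certainty_second_order(0.16, 0.16, 0.19), 0)
  # one sigma from the criterion, either side: 2*pnorm(1) - 1
  expect_equal(certainty_second_order(0.35, 0.16, 0.19), 2 * pnorm(1) - 1)
  expect_equal(certainty_second_order(-0.03, 0.16, 0.19), 2 * pnorm(1) - 1)
  expect_equal(certainty_second_order(100, 0, 0.2), 1, tolerance = 1e-12)
  expect_error(certainty_second_order(0, 0, -1), "positive")
})

test_that("first-order evidence is the signed distance to the criterion", {
  expect_equal(evidence_first_order(0.16, 0.16), 0)
  expect_equal(evidence_first_order(0.26, 0.16), 0.1)
  expect_equal(evidence_first_order(-0.04, 0.16), -0.2)
})

test_that("second-order criteria sit at equal certainty levels (inversion oracle)", {
  p <- model_params("second_order", 1, 1, 0, n_yes = 3)
  got <- interior(p, "low")
  # oracle: invert certainty_second_order numerically at levels 1/3, 2/3
  # on each side of the criterion
  invert <- function(level, side) {
    stats::uniroot(function(x) certainty_second_order(x, 0, 1) - level,
                   interval = c(0, 10) * side, tol = 1e-10)$root
  }
  want <- sort(c(invert(1 / 3, -1), invert(2 / 3, -1), 0,
                 invert(1 / 3, 1), invert(2 / 3, 1)))
  expect_equal(got, want, tolerance = 1e-7)
})

test_that("second-order criteria are translation- and scale-equivariant", {
  base <- model_params("second_order", 0.19, 0.24, 0, n_yes = 2)
  shifted <- model_params("second_order", 0.19, 0.24, 0.16, n_yes = 2)
  expect_equal(interior(shifted, "high"), interior(base, "high") + 0.16)
  doubled <- model_params("second_order", 0.38, 0.48, 0, n_yes = 2)
  expect_equal(interior(doubled, "low"), 2 * interior(base, "low"))
})

test_that("second-order equal-certainty placement is equal-width in probability space", {
  for (ny in 1:5) {
    p <- model_params("second_order", 0.19, 0.24, 0.16, n_yes = ny)
    for (nz in c("low", "high")) {
      q <- pnorm((interior(p, nz) - 0.16) / sigma_for(p, nz))
      # q-space: n_yes equal bins on (0, 1/2), 6 - n_yes on (1/2, 1)
      want <- sort(unique(c(seq(0, 0.5, length.out = ny + 1),
                            seq(0.5, 1, length.out = 7 - ny))))
      expect_equal(q, want[want > 0 & want < 1], tolerance = 1e-10)
    }
  }
})

test_that("first-order criteria divide the per-side spans evenly", {
  p <- model_params("first_order", 0.16, 0.16, 0.16, n_yes = 3,
                    scale_range = 1.11)
  got <- interior(p, "low", d_max = 0.2)
  # spans: a_yes = 0.16 + 1.11 * 0.16 = 0.3376; a_no = 0.2 + 0.1776 - 0.16
  a_yes <- 0.16 + 1.11 * 0.16
  a_no <- 0.2 + 1.11 * 0.16 - 0.16
  want <- sort(c(0.16 - (1:2) * a_yes / 3, 0.16, 0.16 + (1:2) * a_no / 3))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[1:2], c(-0.0651, 0.0475), tolerance = 1e-3)
  expect_equal(got[4:5], c(0.2325, 0.3051), tolerance = 1e-3)
})

test_that("shared_max placement uses the larger span on both sides", {
  p <- model_params("first_order", 0.16, 0.16, 0.16, n_yes = 3,
                    scale_range = 1.11)
  got <- interior(p, "low", d_max = 0.2, placement = "shared_max")
  m <- max(0.16 + 1.11 * 0.16, 0.2 + 1.11 * 0.16 - 0.16)
  want <- sort(c(0.16 - (1:2) * m / 3, 0.16, 0.16 + (1:2) * m / 3))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("degenerate first-order cases collapse as expected", {
  # zero scale range: spans reduce to {c, d_max - c}, independent of sigma
  p_a <- model_params("first_order", 0.1, 0.3, 0.1, n_yes = 3,
                      scale_range = 0)
  expect_equal(interior(p_a, "low"), interior(p_a, "high"))
  expect_equal(range(interior(p_a, "low")),
               c(0.1 - 2 * 0.1 / 3, 0.1 + 2 * 0.1 / 3))
  # equal spreads: identical criteria in both noise conditions
  p_b <- model_params("first_order", 0.16, 0.16, 0.16, n_yes = 2,
                      scale_range = 1.11)
  expect_equal(interior(p_b, "low"), interior(p_b, "high"))
  # criterion outside the scale range is rejected
  p_c <- model_params("first_order", 0.01, 0.01, 0.39, n_yes = 3,
                      scale_range = 0.1)
  expect_error(place_criteria(p_c, "low", d_max = 0.2), "scale range")
})

test_that("extreme mapping values leave one side without interior criteria", {
  for (ny in c(1L, 5L)) {
    p <- model_params("second_order", 0.2, 0.25, 0.16, n_yes = ny)
    crit <- place_criteria(p, "low")
    expect_equal(nrow(crit), 7L)          # always 6 bins
    expect_equal(sum(is.finite(crit$position_s)), 5L)
    expect_true(all(diff(crit$position_s[is.finite(crit$position_s)]) > 0))
  }
  expect_error(model_params("second_order", 0.2, 0.25, 0.16, n_yes = 6),
               "between 1 and 5")
})

test_that("12-bin 2IFC criteria match the certainty-inversion oracle", {
  p <- model_params("second_order", 1, 1, 0)
  got <- place_criteria_2ifc(p, "low")$position_s
  got <- got[is.finite(got)]
  invert <- function(level) {
    stats::uniroot(function(x) certainty_second_order(x, 0, 1) - level,
                   interval = c(0, 10), tol = 1e-10)$root
  }
  pos <- vapply((1:5) / 6, invert, numeric(1))
  expect_equal(got, sort(c(-pos, 0, pos)), tolerance = 1e-7)
  expect_equal(length(got), 11L)          # 12 bins, 6 per side
  # criterion-shift equivariance
  p_s <- model_params("second_order", 1, 1, 0.05)
  got_s <- place_criteria_2ifc(p_s, "low")$position_s
  expect_equal(got_s[is.finite(got_s)], got + 0.05)
})

test_that("first-order 12-bin criteria use the symmetric scale range", {
  p <- model_params("first_order", 0.2, 0.2, 0.02, scale_range = 1)
  delta_max <- 0.3
  got <- place_criteria_2ifc(p, "low", delta_max = delta_max)$position_s
  got <- got[is.finite(got)]
  half <- delta_max + 1 * 0.2
  want <- sort(c(0.02 - (1:5) * (0.02 + half) / 6, 0.02,
                 0.02 + (1:5) * (half - 0.02) / 6))
  expect_equal(got, want, tolerance = 1e-12)
})
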