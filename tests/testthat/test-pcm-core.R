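test_that("category probabilities match the model formula and its identities", {
  # dichotomous symmetry at theta = threshold
  expect_equal(category_probability(0, 0), c(0.5, 0.5))

  # hand-derived three-category case: (1, e, 1) / (2 + e)
  p <- category_probability(0, c(-1, 1))
  expect_equal(p, c(1, exp(1), 1) / (2 + exp(1)), tolerance = 1e-12)

  # adjacent-category identity: at theta = delta_k, categories k-1 and k
  # are equiprobable
  thr <- c(-0.7, 0.2, 1.1)
  for (k in seq_along(thr)) {
    p <- category_probability(thr[k], thr)
    expect_equal(p[k], p[k + 1], tolerance = 1e-12)
  }

  # agreement with the enumeration oracle across a parameter sweep
  set.seed(11)
  for (rep in 1:20) {
    m <- sample(1:5, 1)
    thr <- sort(rnorm(m, sd = 1.5))
    th <- runif(1, -10, 10)
    expect_equal(category_probability(th, thr),
                 enum_category_prob(th, thr), tolerance = 1e-10)
  }
})

test_that("probabilities are a proper distribution over a wide theta range", {
  thr <- c(-2.5, -0.5, 1, 3)
  for (th in seq(-10, 10, by = 0.5)) {
    p <- category_probability(th, thr)
    expect_equal(sum(p), 1, tolerance = 1e-14)
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(category_probability(NA, 0), "finite")
  expect_error(category_probability(0, c(1, Inf)), "finite")
})

test_that("expected score has the right limits, monotonicity and slope", {
  thr <- seven_item_thresholds()[1:3]
  M <- sum(lengths(thr))
  expect_lt(expected_score(-30, thr), 1e-6)
  expect_gt(expected_score(30, thr), M - 1e-6)
  expect_equal(expected_score(0, list(a = 0)), 0.5)

  grid <- seq(-6, 6, by = 0.05)
  es <- expected_score(grid, thr)
  expect_true(all(diff(es) > 0))

  # information equals the derivative of the expected score
  h <- 1e-5
  slope <- (expected_score(grid + h, thr) - expected_score(grid - h, thr)) / (2 * h)
  expect_equal(test_information(grid, thr), slope, tolerance = 1e-6)

  expect_error(expected_score(0, list()), "empty")
})

test_that("item information is non-negative, additive, and 0.25 for a dichotomous item at its threshold", {
  expect_equal(item_information(0.3, 0.3), 0.25)
  thr <- seven_item_thresholds()
  grid <- seq(-5, 5, by = 0.25)
  tot <- test_information(grid, thr[1:2])
  expect_equal(tot, item_information(grid, thr[[1]]) +
                 item_information(grid, thr[[2]]), tolerance = 1e-12)
  expect_true(all(test_information(grid, thr) >= 0))
})
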