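make_ip <- function(thr) {
  # item_parameters shell around known thresholds (bypasses estimation)
  structure(list(thresholds = thr,
                 locations = vapply(thr, mean, numeric(1)),
                 normalization = "sum_locations_zero",
                 convergence = list(converged = TRUE, iterations = 0L,
                                    grad_norm = 0),
                 logLik = NA_real_, n_used = NA_integer_,
                 recoding = list(), item_meta = NULL),
            class = "item_parameters")
}

test_that("ability estimates are symmetric, monotone and finite where they should be", {
  # antisymmetric instrument: half of the maximum score maps to theta = 0
  thr <- list(a = c(-1.5, -0.5, 0.5, 1.5), b = c(-1, 1))
  ip <- make_ip(thr)
  X <- rbind(c(2, 1), c(2, 2), c(0, 0), c(4, 2))
  colnames(X) <- c("a", "b")
  rm <- response_matrix(X, item_meta = data.frame(
    id = c("a", "b"), polarity = "negative", max_category = c(4, 2)))
  pe <- estimate_persons(rm, ip, method = "WLE")
  expect_equal(pe$theta[1], 0, tolerance = 1e-8)   # raw 3 of 6
  expect_true(all(is.finite(pe$theta)))
  expect_true(pe$extreme[3] && pe$extreme[4])
  # monotone in raw score for the complete item set
  expect_true(all(diff(pe$theta[order(pe$raw_score)]) > 0))

  mle <- estimate_persons(rm, ip, method = "MLE")
  expect_equal(mle$theta[3], -Inf)
  expect_equal(mle$theta[4], Inf)
  expect_true(all(is.finite(mle$theta[1:2])))
})

test_that("WLE recovers simulated abilities (r > 0.9 with 7 five-category items)", {
  thr <- seven_item_thresholds()
  rm <- simulate_pcm(unidim_spec(2000, thr, seed = 201))
  fit <- fit_cml(rm)
  pe <- estimate_persons(rm, fit)
  truth <- attr(rm, "truth")$theta[, 1]
  expect_gt(cor(pe$theta, truth), 0.9)
  expect_true(all(pe$se > 0))
  # SE agrees with the information at the estimate
  i <- which(!pe$extreme)[1]
  expect_equal(pe$se[i],
               1 / sqrt(test_information(pe$theta[i], fit)), tolerance = 1e-6)
})

test_that("persons with no observed responses are rejected", {
  thr <- list(a = c(-1, 1), b = c(-0.5, 0.5))
  rm <- simulate_pcm(unidim_spec(50, thr, seed = 202))
  rm$data[3, ] <- NA_integer_
  ip <- make_ip(thr)
  expect_error(estimate_persons(rm, ip), "zero observed items")
})
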