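test_that("conditional ML recovers generating thresholds (unidimensional, n = 2000)", {
  thr <- seven_item_thresholds()
  rm <- simulate_pcm(unidim_spec(2000, thr, seed = 101))
  fit <- fit_cml(rm)

  expect_true(fit$convergence$converged)
  expect_lt(fit$convergence$grad_norm, 1e-8)
  # identification: item locations sum to zero
  expect_lt(abs(sum(fit$locations)), 1e-8)

  truth <- center_locations(thr)
  rmse <- sqrt(mean((unlist(fit$thresholds) - unlist(truth))^2))
  expect_lt(rmse, 0.15)
})

test_that("items simulated from identical thresholds get near-identical estimates", {
  thr <- list(a = c(-1, -0.2, 0.6, 1.4), b = c(-1, -0.2, 0.6, 1.4),
              c = c(-0.5, 0.5))
  rm <- simulate_pcm(unidim_spec(2000, thr, seed = 102))
  fit <- fit_cml(rm)
  # thresholds of a and b agree within sampling error (~2 SE at n = 2000)
  expect_lt(max(abs(fit$thresholds$a - fit$thresholds$b)), 0.25)
})

test_that("estimates are invariant to shifting the person distribution (CML's defining property)", {
  thr <- seven_item_thresholds()[1:5]
  fit0 <- fit_cml(simulate_pcm(unidim_spec(3000, thr, seed = 103,
                                           person_mean = 0)))
  fit1 <- fit_cml(simulate_pcm(unidim_spec(3000, thr, seed = 104,
                                           person_mean = 1)))
  # max over 20 parameters of a difference of two independent estimates:
  # ~3 x sqrt(2) x per-threshold SE at n = 3000
  expect_lt(max(abs(unlist(fit0$thresholds) - unlist(fit1$thresholds))), 0.3)
})

test_that("missing-at-random responses are handled by per-subset conditioning", {
  thr <- seven_item_thresholds()
  rm <- simulate_pcm(unidim_spec(2000, thr, seed = 105, missing_rate = 0.1))
  fit <- fit_cml(rm)
  truth <- center_locations(thr)
  expect_lt(sqrt(mean((unlist(fit$thresholds) - unlist(truth))^2)), 0.2)
  expect_true(fit$convergence$converged)
})

test_that("null categories are collapsed and recorded", {
  thr <- list(a = c(-1, 1), b = c(-0.5, 0.5), c = c(0, 1))
  rm <- simulate_pcm(unidim_spec(400, thr, seed = 106))
  # force category 1 of item a to be unobserved
  rm$data[rm$data[, "a"] == 1L, "a"] <- 2L
  fit <- fit_cml(rm)
  expect_named(fit$recoding, "a")
  expect_equal(fit$recoding$a$to, c(0L, 0L, 1L))
  expect_length(fit$thresholds$a, 1L)
})

test_that("degenerate items are rejected with a preprocessing pointer", {
  thr <- list(a = c(-1, 1), b = c(-0.5, 0.5))
  rm <- simulate_pcm(unidim_spec(200, thr, seed = 107))
  rm$data[, "a"] <- 1L
  expect_error(fit_cml(rm), "fewer than 2 observed categories")
})
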