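test_that("simulation respects the spec: saturation, determinism, validation", {
  thr <- seven_item_thresholds()[1:3]
  sat <- simulate_pcm(simulation_spec(50, thr, person_mean = 10,
                                      person_sd = 1e-6, seed = 801))
  expect_true(all(sat$data == 4L))

  a <- simulate_pcm(unidim_spec(200, thr, seed = 802))
  b <- simulate_pcm(unidim_spec(200, thr, seed = 802))
  expect_identical(a$data, b$data)
  expect_identical(a$person_meta, b$person_meta)

  err <- tryCatch(simulation_spec(1, list(bad = NA), rho = 3, seed = 1),
                  error = identity)
  expect_match(conditionMessage(err), "n")
  expect_match(conditionMessage(err), "thresholds")
  expect_match(conditionMessage(err), "rho")
  expect_error(simulation_spec(100, thr, missing_rate = 1, seed = 1),
               "missing_rate")
  expect_error(inject_dif(unidim_spec(100, thr, seed = 1),
                          dif = list(item = "zz", shift = 1,
                                     covariate = "age", cut = 30)),
               "zz")
})

test_that("empirical category frequencies match theory within Monte Carlo error", {
  d <- c(-0.8, 0, 0.9)
  rm <- simulate_pcm(simulation_spec(5000, list(a = d, b = c(-1, 1)),
                                     person_mean = 0.4, person_sd = 1e-9,
                                     seed = 803))
  p <- category_probability(0.4, d)
  obs <- tabulate(rm$data[, 1] + 1L, nbins = 4) / 5000
  se <- sqrt(p * (1 - p) / 5000)
  expect_true(all(abs(obs - p) < 3 * se + 1e-9))
})

test_that("MCAR masking hits the requested rate and never empties a person", {
  thr <- seven_item_thresholds()
  rm <- simulate_pcm(unidim_spec(3000, thr, seed = 804, missing_rate = 0.15))
  rate <- mean(is.na(rm$data))
  expect_lt(abs(rate - 0.15), 0.01)
  expect_true(all(rowSums(!is.na(rm$data)) > 0))
})

test_that("the scale preset encodes the study-like geometry", {
  spec <- pss_like_preset(seed = 9)
  expect_equal(spec$n, 793L)
  expect_equal(length(spec$thresholds), 14L)
  expect_true(all(lengths(spec$thresholds) == 4L))
  expect_equal(sum(spec$item_trait == 1L), 7L)
  expect_equal(spec$rho, 0.5)
  expect_equal(spec$person_mean, 0.88)
  expect_equal(spec$person_sd, 1.57)
  neg <- paste0("q", c(1, 2, 3, 8, 11, 12, 14))
  negloc <- vapply(spec$thresholds[neg], mean, numeric(1))
  expect_lt(abs(mean(negloc) - 0.58), 0.05)
  # the top two negative items are q1 and q11
  expect_setequal(names(sort(negloc, decreasing = TRUE))[1:2], c("q1", "q11"))

  rm <- simulate_pcm(spec)
  expect_s3_class(rm, "resp_matrix")
  expect_true(all(rm$data %in% 0:4))
  expect_true(all(c("gender", "age") %in% names(rm$person_meta)))
})
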