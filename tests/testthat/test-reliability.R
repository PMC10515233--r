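test_that("the reliability-information relation and its inverse agree with the classical anchor points", {
  expect_equal(psi_from_information(10 / 3), 0.7, tolerance = 1e-12)
  expect_equal(psi_from_information(5), 0.8, tolerance = 1e-12)
  expect_equal(information_for_psi(0.7), 10 / 3, tolerance = 1e-9)
  expect_equal(information_for_psi(0.8), 5, tolerance = 1e-9)
  # clipping below TI = 1
  expect_equal(psi_from_information(c(0.2, 1)), c(0, 0))
  expect_error(psi_from_information(-1), ">= 0")
})

test_that("threshold ordering check localizes disordered adjacent pairs", {
  ip <- list(a = c(-2, -1, 0, 1), b = c(-1, 0.5, 0.2, 1))
  chk <- ordered_thresholds_check(ip)
  expect_false(chk$disordered[1])
  expect_true(chk$disordered[2])
  expect_equal(chk$pairs[2], "2/3")
  expect_equal(chk$max_gap[2], 0.3, tolerance = 1e-12)
})

test_that("a rarely used middle category produces disordered thresholds in simulation", {
  # second threshold far below the first: category 1 nearly skipped
  thr <- list(a = c(1.5, -1.5, 0.5), b = c(-1, 0, 1), c = c(-0.5, 0, 0.5))
  hits <- vapply(1:5, function(s) {
    rm <- simulate_pcm(unidim_spec(1500, thr, seed = 600 + s))
    ordered_thresholds_check(fit_cml(rm))$disordered[1]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("targeting summary reports person and item distributions on one scale", {
  thr <- center_locations(seven_item_thresholds())
  rm <- simulate_pcm(unidim_spec(2000, thr, seed = 601, person_sd = 1))
  fit <- fit_cml(rm)
  pe <- estimate_persons(rm, fit)
  ts <- targeting_summary(pe, fit)
  expect_lt(abs(ts$person_mean - 0), 0.1)
  expect_equal(ts$item_mean, 0, tolerance = 1e-8)
  expect_equal(sum(ts$bins$persons), sum(is.finite(pe$theta)))
  expect_equal(sum(ts$bins$thresholds), sum(lengths(fit$thresholds)))
  expect_warning(targeting_summary(pe[1, ], fit), "SD undefined")
})

test_that("reliability profile: intervals, coverage partition and threshold coverage", {
  thr <- seven_item_thresholds()
  rm <- simulate_pcm(unidim_spec(2000, thr, seed = 602,
                                 person_mean = 0.9, person_sd = 1.6))
  fit <- fit_cml(rm)
  pe <- estimate_persons(rm, fit)
  prof <- reliability_profile(fit, pe)

  expect_true(all(prof$profile$tif >= 0))
  expect_true(all(prof$profile$psi < 1))
  expect_equal(nrow(prof$intervals), 1L)
  # PSI at the interpolated endpoints equals the threshold
  lo <- prof$intervals[1, "lower"]; hi <- prof$intervals[1, "upper"]
  expect_equal(psi_from_information(test_information(c(lo, hi), fit)),
               c(0.7, 0.7), tolerance = 1e-4)
  expect_equal(sum(prof$coverage), 100, tolerance = 0.1)

  # coverage agrees with the long-run value implied by the generating
  # person distribution over the fitted interval (approximately: observed
  # locations carry estimation noise)
  longrun <- 100 * (pnorm((hi - 0.9) / 1.6) - pnorm((lo - 0.9) / 1.6))
  expect_lt(abs(prof$coverage["inside"] - longrun), 6)

  # internal consistency: recompute the partition from the estimates
  th <- pe$theta[is.finite(pe$theta)]
  expect_equal(unname(prof$coverage["inside"]),
               100 * mean(th >= lo & th <= hi), tolerance = 0.01)
  expect_equal(unname(prof$threshold_coverage["above_max"]),
               100 * mean(th > max(unlist(fit$thresholds))))

  # adding an item never decreases the information anywhere
  tif6 <- test_information(prof$profile$theta, fit, items = names(thr)[1:6])
  expect_true(all(prof$profile$tif - tif6 >= -1e-12))
})

test_that("an uninformative instrument yields an empty reliable range", {
  ip <- list(a = 0, b = 0.5)   # two dichotomous items: max TIF 0.5 < 1
  thr7 <- seven_item_thresholds()
  rm <- simulate_pcm(unidim_spec(100, thr7[1:2], seed = 603))
  fit <- fit_cml(rm)
  pe <- estimate_persons(rm, fit)
  prof <- reliability_profile(ip, NULL)
  expect_equal(nrow(prof$intervals), 0L)
  prof2 <- reliability_profile(ip, pe)
  expect_equal(unname(prof2$coverage["inside"]), 0)
})
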