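well_fitting_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      thr <- seven_item_thresholds()
      rm <- simulate_pcm(unidim_spec(2000, thr, seed = 301))
      fit <- fit_cml(rm)
      pe <- estimate_persons(rm, fit)
      cache <<- list(rm = rm, fit = fit, pe = pe,
                     res = pcm_residuals(rm, fit, pe))
    }
    cache
  }
})

test_that("standardized residuals are centred with unit variance under the model", {
  fx <- well_fitting_fixture()
  z <- fx$res$z
  colm <- colMeans(z, na.rm = TRUE)
  colv <- apply(z, 2, var, na.rm = TRUE)
  expect_lt(max(abs(colm)), 0.05)
  expect_lt(max(abs(colv - 1)), 0.1)
  # extreme persons carry no residuals
  expect_true(all(is.na(z[fx$res$excluded, ])))
  # definitional identity on an arbitrary observed cell
  res <- fx$res
  j <- 1L; i <- which(is.finite(z[, j]))[1L]
  expect_equal(z[i, j],
               (fx$rm$data[i, j] - res$expected[i, j]) /
                 sqrt(res$variance[i, j]))
})

test_that("outfit and infit sit near 1 on correct-model data and flag injected misfit", {
  fx <- well_fitting_fixture()
  ft <- outfit_infit(fx$res)
  expect_true(all(ft$outfit_msq > 0.9 & ft$outfit_msq < 1.1))
  expect_true(all(ft$infit_msq > 0.9 & ft$infit_msq < 1.1))
  expect_lt(abs(mean(ft$outfit_msq) - 1), 0.05)
  expect_lt(abs(mean(ft$infit_msq) - 1), 0.05)

  # responses driven by an independent trait misfit loudly
  rm2 <- fx$rm
  alien <- simulate_pcm(unidim_spec(2000, seven_item_thresholds()[4:5],
                                    seed = 999))
  rm2$data[, 4] <- alien$data[, 1]
  fit2 <- fit_cml(rm2)
  ft2 <- flag_misfit(outfit_infit(pcm_residuals(rm2, fit2)))
  expect_gt(ft2$outfit_msq[4], 1.3)
  expect_true(ft2$msq_high[4])
})

test_that("misfit flags use inclusive boundaries", {
  ft <- data.frame(item = c("a", "b", "c"),
                   outfit_msq = c(1.0, 0.7, 0.638),
                   infit_msq = c(1.0, 0.7, 0.64),
                   outfit_zstd = c(0, -2.0, -5.0),
                   infit_zstd = c(0, 2.0, -5.5))
  fl <- flag_misfit(ft)
  expect_false(any(unlist(fl[1, c("msq_low", "msq_high", "zstd_low", "zstd_high")])))
  # exactly on the boundary: not flagged
  expect_false(fl$msq_low[2]); expect_false(fl$zstd_low[2])
  expect_false(fl$zstd_high[2])
  expect_true(fl$msq_low[3]); expect_true(fl$zstd_low[3])
  expect_true(fl$misfit[3])
})

test_that("degenerate residuals give zero mean squares", {
  fx <- well_fitting_fixture()
  res0 <- fx$res
  res0$z[] <- ifelse(is.finite(res0$z), 0, NA)
  ft <- outfit_infit(res0)
  expect_true(all(ft$outfit_msq == 0))
  expect_true(all(flag_misfit(ft)$msq_low))
})

test_that("subsampled ZSTD is deterministic, degenerates to the plain statistic, and deflates large-sample inflation", {
  fx <- well_fitting_fixture()
  # degenerate subsample = whole sample reproduces the plain ZSTD
  full <- outfit_infit(fx$res)
  sub1 <- subsampled_zstd(fx$rm, fx$fit, k = 1, n_sub = nrow(fx$rm$data),
                          seed = 7)
  expect_equal(sub1$outfit_zstd_mean, full$outfit_zstd, tolerance = 1e-12)
  expect_equal(sub1$infit_zstd_mean, full$infit_zstd, tolerance = 1e-12)

  # fixed seed: bit-identical repeats
  a <- subsampled_zstd(fx$rm, fx$fit, k = 5, n_sub = 300, seed = 13)
  b <- subsampled_zstd(fx$rm, fx$fit, k = 5, n_sub = 300, seed = 13)
  expect_identical(a, b)

  # on well-fitting data the subsample average shrinks |ZSTD| overall
  s <- subsampled_zstd(fx$rm, fx$fit, k = 40, n_sub = 300, seed = 17)
  expect_lt(mean(abs(s$outfit_zstd_mean)), mean(abs(full$outfit_zstd)) + 0.3)
  expect_true(all(abs(s$outfit_zstd_mean) < 2))
  expect_true(all(abs(s$infit_zstd_mean) < 2))

  expect_error(subsampled_zstd(fx$rm, fx$fit, n_sub = 1e6), "exceeds")
})
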