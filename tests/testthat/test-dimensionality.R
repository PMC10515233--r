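test_that("residual PCA eigenvalues behave like a correlation spectrum", {
  thr <- seven_item_thresholds()
  rm <- simulate_pcm(unidim_spec(2000, thr, seed = 401))
  fit <- fit_cml(rm)
  rep <- dimensionality_report(rm, fit)
  # trace: eigenvalues sum to the item count, all non-negative
  expect_equal(sum(rep$eigenvalues), 7, tolerance = 1e-8)
  expect_true(all(rep$eigenvalues >= -1e-10))
  # unidimensional truth: first eigenvalue stays below 2
  expect_lt(rep$eigenvalues[1], 2)
  expect_equal(assess_unidimensionality(rep)$verdict, "unidimensional")
})

test_that("two weakly correlated trait clusters are detected and separated by loading sign", {
  spec <- pss_like_preset(n = 2000, rho = 0.3, seed = 402)
  rm <- simulate_pcm(spec)
  fit <- fit_cml(rm)
  rep <- dimensionality_report(rm, fit)
  expect_gte(rep$eigenvalues[1], 2)
  expect_equal(assess_unidimensionality(rep)$verdict, "multidimensional")
  # first-contrast loadings split the wording clusters by sign
  neg <- rm$item_meta$polarity == "negative"
  expect_true(abs(mean(sign(rep$loadings[neg])) -
                  mean(sign(rep$loadings[!neg]))) == 2)
})

test_that("verdict is monotone in the trait correlation", {
  verdicts <- vapply(c(1.0, 0.3), function(rho) {
    rm <- simulate_pcm(pss_like_preset(n = 2000, rho = rho, seed = 403))
    fit <- fit_cml(rm)
    assess_unidimensionality(dimensionality_report(rm, fit))$verdict
  }, character(1))
  expect_equal(verdicts, c("unidimensional", "multidimensional"))
})

test_that("residual correlation screening flags duplicated items and spares independent ones", {
  thr <- seven_item_thresholds()
  rm <- simulate_pcm(unidim_spec(2000, thr, seed = 404))
  # make item 7 a literal copy of item 1
  rm$data[, 7] <- rm$data[, 1]
  fit <- fit_cml(rm)
  q3 <- residual_correlations(pcm_residuals(rm, fit))
  expect_true(any(q3$flagged$item1 == "q1" & q3$flagged$item2 == "q7"))
  expect_gt(q3$cor["q1", "q7"], 0.8)

  # i.i.d. residuals: no flags
  rm2 <- simulate_pcm(unidim_spec(2000, thr, seed = 405))
  q32 <- residual_correlations(pcm_residuals(rm2, fit_cml(rm2)))
  expect_equal(nrow(q32$flagged), 0L)
})

test_that("the relative cutoff rule works on a plain correlation matrix", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.5
  R[1, 3] <- R[3, 1] <- -0.1
  R[2, 3] <- R[3, 2] <- -0.1
  rownames(R) <- colnames(R) <- c("a", "b", "c")
  q3 <- residual_correlations(R)
  expect_equal(q3$mean_r, 0.1, tolerance = 1e-12)
  expect_equal(q3$cutoff, 0.3, tolerance = 1e-12)
  expect_equal(nrow(q3$flagged), 1L)
  expect_equal(q3$flagged$item1, "a")
  expect_equal(q3$flagged$item2, "b")
})
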