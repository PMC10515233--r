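test_that("no spurious DIF on a homogeneous population and full recovery of an injected shift", {
  thr <- seven_item_thresholds()
  rm0 <- simulate_pcm(unidim_spec(2000, thr, seed = 501))
  g <- rep(c("A", "B"), length.out = 2000)
  rep0 <- dif_two_group(rm0, g)
  expect_true(all(rep0$table$dif_size < 0.2))
  expect_false(any(rep0$table$flag))

  # +0.6 logit shift on item q4 for the flagged group
  spec <- inject_dif(unidim_spec(2000, thr, seed = 502),
                     dif = list(item = "q4", shift = 0.6,
                                group = rep(c(FALSE, TRUE), 1000)))
  rm1 <- simulate_pcm(spec)
  rep1 <- dif_two_group(rm1, ifelse(attr(rm1, "truth")$dif_group, "B", "A"))
  i4 <- rep1$table$item == "q4"
  expect_lt(abs(rep1$table$dif_size[i4] - 0.6), 0.1)
  expect_true(rep1$table$flag[i4])
  expect_false("q4" %in% rep1$anchors)
  expect_lt(rep1$p_value, 0.01)
})

test_that("anchoring distinguishes item DIF from pure group impact", {
  thr <- seven_item_thresholds()
  # shifting every item equally is indistinguishable from an ability shift
  spec <- inject_dif(unidim_spec(2000, thr, seed = 503),
                     dif = list(item = names(thr), shift = 0.6,
                                group = rep(c(FALSE, TRUE), 1000)))
  rm <- simulate_pcm(spec)
  rep <- dif_two_group(rm, ifelse(attr(rm, "truth")$dif_group, "B", "A"))
  expect_true(all(rep$table$dif_size < 0.2))

  # and the metric is invariant to an overall ability shift of one group
  spec2 <- unidim_spec(2000, thr, seed = 504)
  rm2 <- simulate_pcm(spec2)
  g <- rep(c("A", "B"), 1000)
  rep2 <- dif_two_group(rm2, g)
  expect_true(all(rep2$table$dif_size < 0.2))
})

test_that("zero-shift injection reproduces the base generation exactly", {
  thr <- seven_item_thresholds()[1:3]
  base <- simulate_pcm(unidim_spec(300, thr, seed = 505))
  same <- simulate_pcm(inject_dif(unidim_spec(300, thr, seed = 505),
                                  dif = list(item = "q1", shift = 0,
                                             covariate = "age", cut = 31)))
  expect_identical(base$data, same$data)
})

test_that("split search finds an injected covariate cut and reports no split under the null", {
  thr <- seven_item_thresholds()
  # DIF only for persons above age 30, several items
  spec <- inject_dif(unidim_spec(2000, thr, seed = 506),
                     dif = list(item = c("q2", "q5"), shift = 0.8,
                                covariate = "age", cut = 30))
  rm <- simulate_pcm(spec)
  found <- dif_split_search(rm, "age", min_group = 300)
  expect_false(is.null(found$split))
  ages <- sort(unique(rm$person_meta$age))
  expect_lte(abs(which(ages == found$split) - which(ages == 30)), 2)
  expect_lt(found$p_adjusted, 0.05)

  # covariate unrelated to responses: no split
  rm0 <- simulate_pcm(unidim_spec(800, thr, seed = 507))
  none <- dif_split_search(rm0, "age", min_group = 250)
  expect_null(none$split)

  # constant covariate: no admissible cut
  const <- dif_split_search(rm0, rep(1, 800), min_group = 50)
  expect_null(const$split)
  expect_match(const$reason, "no admissible")
})
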