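# Independent oracles used across the suite. These deliberately avoid the
# package's recursion/optimization code paths: probabilities from the raw
# model formula, elementary symmetric functions by exhaustive enumeration.

# Category probabilities straight from the defining expression.
enum_category_prob <- function(theta, thresholds) {
  num <- exp(c(0, cumsum(theta - thresholds)))
  num / sum(num)
}

# Elementary symmetric functions by summing over every response pattern.
enum_esf <- function(thresholds_by_item) {
  psi <- lapply(thresholds_by_item, function(d) exp(c(0, -cumsum(d))))
  cats <- lapply(psi, function(p) seq_along(p) - 1L)
  patterns <- expand.grid(cats)
  gamma <- rep(0, sum(vapply(cats, max, integer(1))) + 1L)
  for (row in seq_len(nrow(patterns))) {
    x <- as.integer(patterns[row, ])
    r <- sum(x)
    gamma[r + 1L] <- gamma[r + 1L] +
      prod(mapply(function(p, xi) p[xi + 1L], psi, x))
  }
  gamma
}

# Small unidimensional simulation helper.
unidim_spec <- function(n, thresholds, seed, person_mean = 0,
                        person_sd = 1.5, ...) {
  simulation_spec(n = n, thresholds = thresholds,
                  person_mean = person_mean, person_sd = person_sd,
                  seed = seed, ...)
}

# Seven five-category items with mildly spread locations; a compact
# stand-in instrument for simulation tests.
seven_item_thresholds <- function() {
  loc <- c(-0.9, -0.6, -0.2, 0.1, 0.4, 0.7, 1.0)
  out <- lapply(loc, function(L) L + c(-1.2, -0.4, 0.4, 1.2))
  names(out) <- paste0("q", seq_along(out))
  out
}

# Sum-to-zero-location centering, for comparing estimates with truth.
center_locations <- function(thr) {
  shift <- mean(vapply(thr, mean, numeric(1)))
  lapply(thr, function(d) d - shift)
}
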