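#' Elementary symmetric functions for the partial credit model
#'
#' Computes, for a set of items with step thresholds, the elementary
#' symmetric functions gamma_r of the category terms
#' `psi_{i,x} = exp(-sum_{k <= x} delta_{ik})`: for every attainable total
#' score r = 0..sum(m_i), gamma_r is the sum over all response patterns with
#' that total of the product of their psi terms. These normalize the
#' conditional likelihood (the person parameter cancels given the raw
#' score). The recursion convolves one item at a time and is carried out in
#' log space, so it is overflow-safe for any threshold magnitudes.
#'
#' @param thresholds_by_item List of numeric threshold vectors, one per item.
#' @param items Optional subset of items (names or indices) to restrict to;
#'   supports per-subset tables under missing data.
#' @return An object of class `esf_table`: list with `log_gamma` (numeric
#'   vector of length 1 + sum(m_i), scores 0..max) and `gamma`
#'   (exponentiated, may overflow to Inf for extreme parameters -- use
#'   `log_gamma` in computations).
#' @examples
#' # two dichotomous items: gamma_1 = eps1 + eps2, gamma_2 = eps1 * eps2
#' elementary_symmetric(list(0.5, -0.2))$gamma
#' @export
elementary_symmetric <- function(thresholds_by_item, items = NULL) {
  thr <- get_thresholds(thresholds_by_item, items)
  if (length(thr) == 0L) stop("item subset is empty", call. = FALSE)
  lg <- log_esf(log_psi(thr))
  structure(list(log_gamma = lg, gamma = exp(lg),
                 max_score = length(lg) - 1L),
            class = "esf_table")
}

# log psi rows per item: element x+1 = -cumsum(delta)[x], with 0 for x = 0
log_psi <- function(thr) lapply(thr, function(d) c(0, -cumsum(d)))

# log-space convolution of two coefficient vectors given as logs
log_conv <- function(g, lp) {
  out <- rep(-Inf, length(g) + length(lp) - 1L)
  for (x in seq_along(lp)) {
    idx <- x:(x + length(g) - 1L)
    a <- out[idx]; b <- g + lp[x]
    m <- pmax(a, b)
    m[!is.finite(m)] <- 0
    out[idx] <- m + log(exp(a - m) + exp(b - m))
  }
  out
}

# full log ESF vector over scores 0..sum(m_i)
log_esf <- function(lpsi) Reduce(log_conv, lpsi, accumulate = FALSE, init = 0)

# leave-one-out log ESFs via prefix/suffix convolutions:
# element i = log ESF of all items except i
log_esf_loo <- function(lpsi) {
  I <- length(lpsi)
  pref <- vector("list", I + 1L); pref[[1L]] <- 0
  for (i in seq_len(I)) pref[[i + 1L]] <- log_conv(pref[[i]], lpsi[[i]])
  suf <- vector("list", I + 1L); suf[[I + 1L]] <- 0
  for (i in I:1) suf[[i]] <- log_conv(suf[[i + 1L]], lpsi[[i]])
  lapply(seq_len(I), function(i) log_conv(pref[[i]], suf[[i + 1L]]))
}

#' @export
print.esf_table <- function(x, ...) {
  cat("Elementary symmetric function table: scores 0..", x$max_score,
      "\n", sep = "")
  cat("log gamma: ", paste(signif(utils::head(x$log_gamma, 8L), 4),
                           collapse = " "),
      if (length(x$log_gamma) > 8L) " ..." else "", "\n", sep = "")
  invisible(x)
}
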