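#' Ordinal sum score to interval score conversion table
#'
#' Builds a raw-score-to-logit lookup table for a complete item subset:
#' for every interior raw score r the interval measure theta(r) solves
#' `expected_score(theta) = r` (monotone root-finding, tolerance 1e-8);
#' the extreme scores 0 and max are located by the weighted likelihood
#' estimate, which is finite. Standard errors are
#' `1 / sqrt(test information at theta(r))`. The table is valid only for
#' persons answering every item of the subset.
#'
#' @param ip An `item_parameters` object.
#' @param items Optional item subset (ids); default all items in `ip`.
#' @return Object of class `score_table` (data frame): columns
#'   `raw_score` (0..sum of max categories), `theta`, `se`; attributes
#'   `items` and `extreme_handling` ("WLE").
#' @export
score_to_theta_table <- function(ip, items = NULL) {
  thr <- get_thresholds(ip, items)
  if (length(thr) == 0L) stop("empty item subset", call. = FALSE)
  M <- sum(vapply(thr, length, integer(1)))
  theta <- numeric(M + 1L)
  for (r in 0:M) {
    theta[r + 1L] <- if (r == 0L || r == M) {
      solve_theta(r, thr, "WLE")[1L]
    } else {
      f <- function(th) Reduce(`+`, lapply(thr, function(d)
        pcm_moments(th, d)$mean)) - r
      lo <- -12; hi <- 12
      while (f(lo) > 0 && lo > -40) lo <- lo - 6
      while (f(hi) < 0 && hi < 40) hi <- hi + 6
      stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    }
  }
  if (any(diff(theta) <= 0))
    stop("conversion table is not strictly increasing (should not happen)",
         call. = FALSE)
  se <- 1 / sqrt(Reduce(`+`, lapply(thr, function(d)
    item_information(theta, d))))
  out <- data.frame(raw_score = 0:M, theta = theta, se = se)
  structure(out,
            items = if (is.null(items)) names(thr) else items,
            extreme_handling = "WLE",
            class = c("score_table", "data.frame"))
}

#' Convert raw sum scores through a conversion table
#'
#' Vectorized lookup of interval scores and standard errors for integer
#' raw sum scores. Scores outside the table's range raise an error naming
#' the offending person.
#'
#' @param tbl A `score_table` from [score_to_theta_table()].
#' @param raw_scores Integer vector of raw sum scores on the table's item
#'   subset (complete responses assumed).
#' @return Data frame with `raw_score`, `theta`, `se`, one row per input.
#' @export
apply_score_table <- function(tbl, raw_scores) {
  stopifnot(inherits(tbl, "score_table"))
  rs <- raw_scores
  if (any(!is.finite(rs)) || any(rs != round(rs)))
    stop("raw scores must be integers (persons with missing subset items cannot use the table)",
         call. = FALSE)
  bad <- which(rs < 0 | rs > max(tbl$raw_score))
  if (length(bad))
    stop(sprintf("raw score %d out of range 0..%d for person %d",
                 rs[bad[1L]], max(tbl$raw_score), bad[1L]), call. = FALSE)
  idx <- match(rs, tbl$raw_score)
  data.frame(raw_score = rs, theta = tbl$theta[idx], se = tbl$se[idx])
}

#' @export
print.score_table <- function(x, digits = 3, ...) {
  cat("Ordinal-to-interval score conversion (items: ",
      paste(attr(x, "items"), collapse = ","), ")\n", sep = "")
  cat("extreme scores located by ", attr(x, "extreme_handling"), "\n",
      sep = "")
  print.data.frame(round(as.data.frame(x), digits), row.names = FALSE)
  invisible(x)
}
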