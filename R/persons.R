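#' Estimate person locations
#'
#' Person ability estimates on the logit scale given fitted item
#' parameters. The default is Warm's weighted likelihood estimate (WLE),
#' which is bias-corrected and stays finite for extreme (zero or perfect)
#' raw scores, so every person appears in targeting displays and coverage
#' percentages; plain maximum likelihood (MLE) is available for
#' comparison, with extreme scores mapped to -Inf/Inf.
#'
#' For the partial credit model the raw sum score is sufficient for theta,
#' so estimates are solved once per distinct (observed item subset, raw
#' score) combination. The WLE solves
#' `r - E[R | theta] + I'(theta) / (2 I(theta)) = 0`, where I is the test
#' information of the person's observed items and I' its derivative (the
#' third central moment of the score distribution). Standard errors are
#' `1 / sqrt(I(theta_hat))`.
#'
#' @param rm A [response_matrix()] object.
#' @param ip An `item_parameters` object fitted on a compatible item set.
#' @param method `"WLE"` (default) or `"MLE"`.
#' @return An object of class `person_estimates`: data frame with columns
#'   `theta`, `se`, `raw_score`, `max_score`, `extreme`, `n_items`, and
#'   attribute `method`.
#' @export
estimate_persons <- function(rm, ip, method = c("WLE", "MLE")) {
  stopifnot(inherits(rm, "resp_matrix"), inherits(ip, "item_parameters"))
  method <- match.arg(method)
  X <- recode_like(rm, ip)
  idx <- match(colnames(X), names(ip$thresholds))
  if (anyNA(idx))
    stop("item parameters missing for: ",
         paste(colnames(X)[is.na(idx)], collapse = ", "), call. = FALSE)
  thr_all <- ip$thresholds[idx]
  m <- vapply(thr_all, length, integer(1))

  nobs <- rowSums(!is.na(X))
  if (any(nobs == 0L))
    stop("person(s) with zero observed items: rows ",
         paste(utils::head(which(nobs == 0L), 5L), collapse = ", "),
         call. = FALSE)
  r <- as.integer(rowSums(X, na.rm = TRUE))
  rmax <- as.integer((!is.na(X)) %*% m)
  key <- paste(apply(!is.na(X), 1L, function(b) paste(which(b), collapse = ",")),
               r, sep = "|")

  uniq <- !duplicated(key)
  sol <- matrix(NA_real_, sum(uniq), 2L,
                dimnames = list(key[uniq], c("theta", "se")))
  for (u in which(uniq)) {
    sub <- which(!is.na(X[u, ]))
    est <- solve_theta(r[u], thr_all[sub], method)
    sol[key[u], ] <- est
  }
  out <- data.frame(theta = sol[key, "theta"], se = sol[key, "se"],
                    raw_score = r, max_score = rmax,
                    extreme = r == 0L | r == rmax, n_items = nobs)
  rownames(out) <- rownames(X)
  structure(out, method = method, class = c("person_estimates", "data.frame"))
}

# Solve the (weighted) likelihood equation for one raw score on one item
# subset. Returns c(theta, se).
solve_theta <- function(r, thr, method) {
  M <- sum(vapply(thr, length, integer(1)))
  if (method == "MLE" && (r == 0L || r == M)) {
    th <- if (r == 0L) -Inf else Inf
    return(c(th, Inf))
  }
  f <- if (method == "WLE") {
    function(th) {
      mo <- score_moments(th, thr)
      r - mo$mean + mo$mu3 / (2 * mo$var)
    }
  } else {
    function(th) r - score_moments(th, thr)$mean
  }
  lo <- -12; hi <- 12
  while (f(lo) < 0 && lo > -40) lo <- lo - 6
  while (f(hi) > 0 && hi < 40) hi <- hi + 6
  th <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  info <- score_moments(th, thr)$var
  c(th, 1 / sqrt(info))
}

# Apply the category recoding recorded during fitting to new data, so
# person estimation and residuals line up with the fitted parameters.
recode_like <- function(rm, ip) {
  X <- rm$data
  for (id in names(ip$recoding)) {
    j <- match(id, colnames(X))
    if (is.na(j)) next
    map <- ip$recoding[[id]]
    X[, j] <- map$to[match(X[, j], map$from)]
  }
  X
}

#' @export
print.person_estimates <- function(x, ...) {
  cat(sprintf("Person estimates (%s): n = %d, extreme scores: %d\n",
              attr(x, "method"), nrow(x), sum(x$extreme)))
  ok <- is.finite(x$theta)
  cat(sprintf("theta: mean %.3f, sd %.3f, range [%.2f, %.2f]\n",
              mean(x$theta[ok]), stats::sd(x$theta[ok]),
              min(x$theta[ok]), max(x$theta[ok])))
  invisible(x)
}
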