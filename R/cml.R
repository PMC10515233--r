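#' Fit the partial credit model by conditional maximum likelihood
#'
#' Estimates the item step thresholds of a partial credit model by
#' maximizing the likelihood conditional on each person's raw sum score,
#' which eliminates the person parameters via elementary symmetric
#' functions. Persons are grouped by their observed item subset, so
#' missing responses are handled by conditioning within each subset;
#' persons with extreme raw scores (zero or maximum over their subset)
#' carry no conditional information and are ignored during estimation.
#'
#' Identification: the conditional likelihood is invariant to a uniform
#' shift of all thresholds; the default constraint fixes the sum of item
#' locations (per-item threshold means) to zero, and the constraint used
#' is recorded on the returned object so reports can re-anchor.
#'
#' A category observed zero times makes its step parameter inestimable;
#' such null categories are collapsed into their lower neighbour (the
#' lowest category into its upper neighbour) before fitting, and the
#' recoding is recorded in the result.
#'
#' Optimization: BFGS on the (convex) negative conditional log-likelihood
#' with the analytic gradient, followed by Newton polishing until the
#' gradient norm drops below `tol`.
#'
#' @param rm A [response_matrix()] object.
#' @param tol Convergence tolerance on the gradient norm (default 1e-8).
#' @param max_iter Maximum number of optimizer iterations (default 200).
#' @param normalization Identification constraint; only
#'   `"sum_locations_zero"` is implemented.
#' @return An object of class `item_parameters`: list with `thresholds`
#'   (named list of step parameter vectors, logits), `locations` (per-item
#'   threshold means), `normalization`, `convergence` (iterations, gradient
#'   norm, converged flag), `logLik` (conditional), `n_used`, `recoding`
#'   (per-item category collapsing, if any), `item_meta`.
#' @examples
#' spec <- simulation_spec(n = 300, thresholds = list(a = c(-1, 1), b = c(-0.5, 0.5)),
#'                         seed = 1)
#' fit_cml(simulate_pcm(spec))
#' @export
fit_cml <- function(rm, tol = 1e-8, max_iter = 200,
                    normalization = "sum_locations_zero") {
  stopifnot(inherits(rm, "resp_matrix"))
  normalization <- match.arg(normalization)
  prep <- cml_prepare(rm)
  obj <- cml_objective(prep)
  M <- sum(prep$m)

  fit <- stats::optim(rep(0, M - 1L), obj$nll, obj$grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-13))
  iters <- fit$counts[["gradient"]]
  par <- fit$par
  gn <- sqrt(sum(obj$grad(par)^2))

  # Newton polish: quadratic convergence to the prescribed gradient norm
  polish <- 0L
  while (gn > tol && polish < 25L) {
    H <- stats::optimHess(par, obj$nll, obj$grad)
    step <- tryCatch(solve(H, obj$grad(par)), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- obj$nll(par); s <- 1
    repeat {
      cand <- par - s * step
      if (obj$nll(cand) <= f0 || s < 1e-6) break
      s <- s / 2
    }
    par <- par - s * step
    gn <- sqrt(sum(obj$grad(par)^2))
    polish <- polish + 1L
  }
  if (gn > max(tol, 1e-6) * 100)
    stop(sprintf("conditional ML did not converge: gradient norm %.3e after %d iterations",
                 gn, iters + polish), call. = FALSE)

  delta <- c(par, -sum(par))
  thr <- split(delta, rep(seq_along(prep$m), prep$m))
  # re-anchor so the item locations (threshold means) sum to zero
  shift <- mean(vapply(thr, mean, numeric(1)))
  thr <- lapply(thr, function(d) d - shift)
  names(thr) <- prep$item_ids
  loc <- vapply(thr, mean, numeric(1))

  structure(list(
    thresholds = thr,
    locations = loc,
    normalization = normalization,
    convergence = list(converged = gn <= max(tol, 1e-6) * 100,
                       iterations = as.integer(iters + polish),
                       grad_norm = gn),
    logLik = -obj$nll(par),
    n_used = prep$n_used,
    recoding = prep$recoding,
    item_meta = rm$item_meta),
    class = "item_parameters")
}

# Preprocess for CML: collapse null categories, drop non-informative
# persons, group by observed item subset, and accumulate sufficient
# statistics.
cml_prepare <- function(rm) {
  X <- rm$data
  I <- ncol(X)
  m_max <- rm$item_meta$max_category
  recoding <- list()
  for (i in seq_len(I)) {
    obs <- X[, i][!is.na(X[, i])]
    seen <- sort(unique(obs))
    if (length(seen) < 2L)
      stop(sprintf("item %s has fewer than 2 observed categories; fix in preprocessing",
                   colnames(X)[i]), call. = FALSE)
    full <- 0:m_max[i]
    if (!all(full %in% seen)) {
      # collapse each unobserved category into its lower neighbour
      # (category 0, if unobserved, merges upward); equivalent to mapping
      # observed categories onto consecutive codes 0..m'
      map <- cumsum(full %in% seen) - 1L
      map[map < 0L] <- 0L
      X[, i] <- map[X[, i] + 1L]
      recoding[[colnames(X)[i]]] <- data.frame(from = full, to = map)
    }
  }
  m <- apply(X, 2L, function(v) max(v, na.rm = TRUE))
  nobs <- rowSums(!is.na(X))
  if (any(nobs == 0L))
    stop("persons with no observed responses: rows ",
         paste(utils::head(which(nobs == 0L), 5L), collapse = ", "),
         call. = FALSE)
  r <- rowSums(X, na.rm = TRUE)
  rmax <- as.integer((!is.na(X)) %*% m)
  keep <- r > 0L & r < rmax      # extreme persons: no conditional information
  Xk <- X[keep, , drop = FALSE]

  key <- apply(!is.na(Xk), 1L, function(b) paste(which(b), collapse = ","))
  groups <- lapply(split(seq_len(nrow(Xk)), key), function(rows) {
    sub <- as.integer(strsplit(key[rows[1L]], ",")[[1L]])
    rs <- rowSums(Xk[rows, sub, drop = FALSE])
    list(items = sub,
         nr = tabulate(rs + 1L, nbins = sum(m[sub]) + 1L))
  })
  S <- lapply(seq_len(I), function(i) {
    v <- Xk[, i][!is.na(Xk[, i])]
    vapply(seq_len(m[i]), function(k) sum(v >= k), numeric(1))
  })
  list(m = m, S = S, groups = groups, item_ids = colnames(X),
       n_used = sum(keep), recoding = recoding)
}

# Negative conditional log-likelihood and gradient over the reduced
# parameter vector (last threshold = -sum(others), removing the flat
# direction).
cml_objective <- function(prep) {
  m <- prep$m; I <- length(m); M <- sum(m)
  item_of <- rep(seq_len(I), m)
  Sflat <- unlist(prep$S)
  expand <- function(par) c(par, -sum(par))
  nll_full <- function(delta) {
    thr <- split(delta, item_of)
    lpsi <- log_psi(thr)
    val <- sum(delta * Sflat)
    for (g in prep$groups) {
      lg <- log_esf(lpsi[g$items])
      val <- val + sum(g$nr * lg)
    }
    val
  }
  grad_full <- function(delta) {
    thr <- split(delta, item_of)
    lpsi <- log_psi(thr)
    gr <- Sflat
    offset <- c(0L, cumsum(m))   # parameter offset per item
    for (g in prep$groups) {
      sub <- g$items
      lg <- log_esf(lpsi[sub])
      loo <- log_esf_loo(lpsi[sub])
      scores <- which(g$nr > 0)
      for (j in seq_along(sub)) {
        i <- sub[j]; lgi <- loo[[j]]; lpi <- lpsi[[i]]
        # E[ 1{X_i >= k} | r ] accumulated over represented scores
        for (k in seq_len(m[i])) {
          e <- 0
          for (ri in scores) {
            rr <- ri - 1L
            xs <- k:m[i]
            ok <- xs <= rr & (rr - xs) <= (length(lgi) - 1L)
            if (!any(ok)) next
            xs <- xs[ok]
            e <- e + g$nr[ri] *
              sum(exp(lpi[xs + 1L] + lgi[rr - xs + 1L] - lg[ri]))
          }
          gr[offset[i] + k] <- gr[offset[i] + k] - e
        }
      }
    }
    gr
  }
  list(nll = function(par) nll_full(expand(par)),
       grad = function(par) { g <- grad_full(expand(par)); g[-M] - g[M] })
}

#' @export
print.item_parameters <- function(x, digits = 3, ...) {
  cat("Partial credit model item parameters (conditional ML)\n")
  cat(sprintf("items: %d  persons used: %d  logLik: %.2f\n",
              length(x$thresholds), x$n_used, x$logLik))
  cat(sprintf("converged: %s (iterations %d, gradient norm %.2e)\n",
              x$convergence$converged, x$convergence$iterations,
              x$convergence$grad_norm))
  cat("normalization:", x$normalization, "\n")
  tab <- data.frame(location = round(x$locations, digits),
                    thresholds = vapply(x$thresholds, function(d)
                      paste(round(d, digits), collapse = " "), character(1)))
  print(tab)
  if (length(x$recoding))
    cat("note: null categories collapsed for item(s): ",
        paste(names(x$recoding), collapse = ", "), "\n", sep = "")
  invisible(x)
}
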