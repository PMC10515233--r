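#' Standardized response residuals
#'
#' Standardized residuals `z = (x - E[X]) / sqrt(Var(X))` per person and
#' item. By default (`moments = "conditional"`) the moments are those of
#' the item's response distribution conditional on the person's raw sum
#' score over their observed items -- the same conditioning that drives
#' the estimation, computed via elementary symmetric functions. This
#' makes `E[z] = 0` and `E[z^2] = 1` hold exactly under the model, so the
#' mean-square fit statistics are centred at 1 regardless of test length.
#' The alternative `moments = "theta"` evaluates the unconditional
#' moments at the estimated person locations; these mean squares deflate
#' by roughly `1 - V_i/TIF` under the model because the person estimate
#' absorbs part of each response.
#'
#' Persons with extreme raw scores are excluded either way (their
#' conditional distribution is degenerate); their rows are NA.
#'
#' @param rm A [response_matrix()] object.
#' @param ip Fitted `item_parameters`.
#' @param pe Optional `person_estimates` (computed from `rm` and `ip` when
#'   needed; WLE).
#' @param moments `"conditional"` (default) or `"theta"`.
#' @return An object of class `resid_matrix`: list of matrices `z`
#'   (standardized residuals), `expected`, `variance`, `mu4` (fourth
#'   central moments, used by the standardized fit statistics), plus
#'   `theta`, `excluded` (row indices of extreme persons) and `moments`.
#' @export
pcm_residuals <- function(rm, ip, pe = NULL,
                          moments = c("conditional", "theta")) {
  stopifnot(inherits(rm, "resp_matrix"), inherits(ip, "item_parameters"))
  moments <- match.arg(moments)
  if (is.null(pe)) pe <- estimate_persons(rm, ip)
  X <- recode_like(rm, ip)
  if (nrow(X) != nrow(pe))
    stop("response matrix and person estimates have different sizes",
         call. = FALSE)
  thr <- ip$thresholds[colnames(X)]
  E <- V <- C4 <- matrix(NA_real_, nrow(X), ncol(X),
                         dimnames = dimnames(X))
  use <- !pe$extreme
  if (moments == "theta") {
    for (j in seq_len(ncol(X))) {
      rows <- use & !is.na(X[, j])
      mo <- pcm_moments(pe$theta[rows], thr[[j]])
      E[rows, j] <- mo$mean
      V[rows, j] <- mo$var
      C4[rows, j] <- mo$mu4
    }
  } else {
    m <- vapply(thr, length, integer(1))
    key <- paste(apply(!is.na(X), 1L, function(b)
      paste(which(b), collapse = ",")), pe$raw_score, sep = "|")
    for (kk in unique(key[use])) {
      rows <- which(use & key == kk)
      sub <- which(!is.na(X[rows[1L], ]))
      r <- pe$raw_score[rows[1L]]
      lpsi <- log_psi(thr[sub])
      lg <- log_esf(lpsi)
      loo <- log_esf_loo(lpsi)
      for (j in seq_along(sub)) {
        i <- sub[j]
        xs <- 0:m[i]
        ok <- xs <= r & (r - xs) <= (length(loo[[j]]) - 1L)
        p <- numeric(m[i] + 1L)
        p[ok] <- exp(lpsi[[j]][which(ok)] + loo[[j]][r - xs[ok] + 1L] -
                       lg[r + 1L])
        mu <- sum(xs * p)
        d <- xs - mu
        vv <- sum(p * d^2)
        if (vv < 1e-12) next   # degenerate (e.g. single-item subset)
        E[rows, i] <- mu
        V[rows, i] <- vv
        C4[rows, i] <- sum(p * d^4)
      }
    }
    E[is.na(X)] <- V[is.na(X)] <- C4[is.na(X)] <- NA_real_
  }
  z <- (X - E) / sqrt(V)
  structure(list(z = z, expected = E, variance = V, mu4 = C4,
                 theta = pe$theta, excluded = which(pe$extreme),
                 moments = moments),
            class = "resid_matrix")
}

#' Outfit and infit item statistics
#'
#' Per-item mean-square fit statistics with z-standardized versions.
#' Outfit is the unweighted mean of squared standardized residuals;
#' infit is the information-weighted version
#' `sum((x - E)^2) / sum(Var)`. Both have expectation 1 under the model.
#' ZSTD applies the Wilson-Hilferty cube-root transform,
#' `z = (msq^(1/3) - 1) * 3/q + q/3`, with the model-based variance q^2
#' computed from the fourth conditional moments:
#' outfit `q^2 = sum(mu4 / Var^2) / N^2 - 1/N`,
#' infit `q^2 = sum(mu4 - Var^2) / (sum Var)^2`.
#'
#' @param res A `resid_matrix` from [pcm_residuals()].
#' @param min_n Observations below which an item's statistics are flagged
#'   `low_n` (default 10).
#' @return A `fit_table` data frame with columns `item`, `n`,
#'   `outfit_msq`, `infit_msq`, `outfit_zstd`, `infit_zstd`, `low_n`.
#' @export
outfit_infit <- function(res, min_n = 10) {
  stopifnot(inherits(res, "resid_matrix"))
  items <- colnames(res$z)
  if (is.null(items) || sum(is.finite(res$z)) == 0L)
    stop("residual matrix is empty", call. = FALSE)
  out <- lapply(seq_along(items), function(j) {
    ok <- is.finite(res$z[, j])
    z2 <- res$z[ok, j]^2
    V <- res$variance[ok, j]; C <- res$mu4[ok, j]
    N <- sum(ok)
    u <- mean(z2)
    v <- sum(z2 * V) / sum(V)
    qu2 <- sum(C / V^2) / N^2 - 1 / N
    qv2 <- sum(C - V^2) / sum(V)^2
    data.frame(item = items[j], n = N,
               outfit_msq = u, infit_msq = v,
               outfit_zstd = wilson_hilferty(u, qu2),
               infit_zstd = wilson_hilferty(v, qv2),
               low_n = N < min_n)
  })
  structure(do.call(rbind, out), class = c("fit_table", "data.frame"))
}

wilson_hilferty <- function(msq, q2) {
  q <- sqrt(pmax(q2, 1e-12))
  (msq^(1 / 3) - 1) * 3 / q + q / 3
}

#' Subsample-averaged standardized fit statistics
#'
#' ZSTD grows with sample size under even mild misfit, so large samples
#' flag every item. This recomputes the standardized statistics on `k`
#' random subsamples of `n_sub` persons (drawn without replacement, item
#' parameters and person estimates held fixed from the full fit by
#' default) and reports the per-item mean and SD across draws.
#'
#' @param rm A [response_matrix()] object.
#' @param ip Fitted `item_parameters`.
#' @param k Number of subsamples (default 40).
#' @param n_sub Persons per subsample (default 300).
#' @param seed Integer seed; the draw sequence is fully reproducible.
#' @param refit If `TRUE`, item parameters are re-estimated on each
#'   subsample instead of being held fixed (slower).
#' @return Data frame with per-item `outfit_zstd_mean`, `outfit_zstd_sd`,
#'   `infit_zstd_mean`, `infit_zstd_sd` plus the settings used.
#' @export
subsampled_zstd <- function(rm, ip, k = 40, n_sub = 300, seed = 1,
                            refit = FALSE) {
  stopifnot(inherits(rm, "resp_matrix"))
  n <- nrow(rm$data)
  if (n_sub > n) stop("n_sub exceeds the number of persons", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  set.seed(seed)
  pe <- estimate_persons(rm, ip)
  res <- if (!refit) pcm_residuals(rm, ip, pe)
  draws <- lapply(seq_len(k), function(i) sort(sample.int(n, n_sub)))
  stats_k <- lapply(draws, function(rows) {
    if (refit) {
      sub_rm <- response_matrix(rm$data[rows, , drop = FALSE],
                                item_meta = rm$item_meta)
      ft <- outfit_infit(pcm_residuals(sub_rm, fit_cml(sub_rm)))
    } else {
      sub <- res
      sub$z <- sub$z[rows, , drop = FALSE]
      sub$variance <- sub$variance[rows, , drop = FALSE]
      sub$mu4 <- sub$mu4[rows, , drop = FALSE]
      ft <- outfit_infit(sub)
    }
    ft[, c("outfit_zstd", "infit_zstd")]
  })
  ozs <- sapply(stats_k, `[[`, "outfit_zstd")
  izs <- sapply(stats_k, `[[`, "infit_zstd")
  if (is.null(dim(ozs))) { ozs <- rbind(ozs); izs <- rbind(izs) }
  data.frame(item = colnames(rm$data),
             outfit_zstd_mean = rowMeans(ozs),
             outfit_zstd_sd = apply(ozs, 1L, stats::sd),
             infit_zstd_mean = rowMeans(izs),
             infit_zstd_sd = apply(izs, 1L, stats::sd),
             k = k, n_sub = n_sub)
}

#' Flag misfitting items
#'
#' Applies the conventional acceptance ranges -- mean squares within
#' `msq_range` and standardized statistics within `±zstd_bound` -- to a
#' fit table. Bounds are inclusive: a mean square of exactly 0.7 is not
#' flagged.
#'
#' @param ft A `fit_table` from [outfit_infit()]. Columns
#'   `outfit_zstd`/`infit_zstd` may be replaced by subsample-averaged
#'   values before flagging.
#' @param msq_range Acceptable mean-square range (default `c(0.7, 1.3)`).
#' @param zstd_bound Acceptable |ZSTD| bound (default 2.0).
#' @return The table with added logical columns `msq_low`, `msq_high`,
#'   `zstd_low`, `zstd_high` and a combined `misfit` flag.
#' @export
flag_misfit <- function(ft, msq_range = c(0.7, 1.3), zstd_bound = 2.0) {
  stopifnot(is.data.frame(ft))
  msq <- pmin(ft$outfit_msq, ft$infit_msq)
  msq_hi <- pmax(ft$outfit_msq, ft$infit_msq)
  ft$msq_low <- msq < msq_range[1]
  ft$msq_high <- msq_hi > msq_range[2]
  zmin <- pmin(ft$outfit_zstd, ft$infit_zstd)
  zmax <- pmax(ft$outfit_zstd, ft$infit_zstd)
  ft$zstd_low <- zmin < -zstd_bound
  ft$zstd_high <- zmax > zstd_bound
  ft$misfit <- ft$msq_low | ft$msq_high | ft$zstd_low | ft$zstd_high
  ft
}

#' @export
print.fit_table <- function(x, digits = 3, ...) {
  cat("Item fit statistics\n")
  print.data.frame(cbind(x[1:2], round(x[, setdiff(names(x)[-(1:2)],
    c("low_n", "msq_low", "msq_high", "zstd_low", "zstd_high", "misfit"))],
    digits), x[intersect(names(x), "misfit")]), row.names = FALSE)
  invisible(x)
}
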