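#' Partial credit model category probabilities
#'
#' Response probabilities for one item under Masters' partial credit model.
#' For a person at location `theta` (logits) and an item with step thresholds
#' `thresholds` = (delta_1, ..., delta_m), the probability of category
#' x in 0..m is proportional to `exp(sum_{k <= x} (theta - delta_k))`, with
#' an empty sum for x = 0.
#'
#' @param theta Person location in logits (finite scalar).
#' @param thresholds Numeric vector of finite step thresholds (length m >= 1).
#' @return Numeric vector of length m + 1 with the probabilities of
#'   categories 0..m; entries are positive and sum to 1.
#' @examples
#' category_probability(0, c(-1, 1))
#' @export
category_probability <- function(theta, thresholds) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("`theta` must be a single finite number", call. = FALSE)
  if (!is.numeric(thresholds) || length(thresholds) < 1L ||
      any(!is.finite(thresholds)))
    stop("`thresholds` must be a non-empty finite numeric vector",
         call. = FALSE)
  lp <- c(0, cumsum(theta - thresholds))
  p <- exp(lp - max(lp))
  p / sum(p)
}

# Category probabilities for many persons at once: returns n x (m+1) matrix.
pcm_prob_matrix <- function(theta, thresholds) {
  m <- length(thresholds)
  lp <- outer(theta, 0:m) - rep(c(0, cumsum(thresholds)), each = length(theta))
  lp <- lp - apply(lp, 1L, max)
  p <- exp(lp)
  p / rowSums(p)
}

# Central moments of the category distribution at theta for one item.
# Returns list(mean, var, mu3, mu4); vectorized over theta.
pcm_moments <- function(theta, thresholds) {
  p <- pcm_prob_matrix(theta, thresholds)
  x <- 0:length(thresholds)
  mu <- drop(p %*% x)
  d <- outer(mu, x, function(a, b) b - a)
  list(mean = mu,
       var  = rowSums(p * d^2),
       mu3  = rowSums(p * d^3),
       mu4  = rowSums(p * d^4))
}

#' Item information under the partial credit model
#'
#' The Fisher information one item contributes at person location `theta`:
#' the conditional variance of the item score, `Var(X | theta)`. For the
#' whole instrument, informations add across items (test information).
#'
#' @param theta Numeric vector of person locations (logits).
#' @param thresholds Step thresholds of the item.
#' @return Numeric vector of informations, same length as `theta`.
#' @seealso [test_information()]
#' @examples
#' item_information(0, 0)  # dichotomous item at its threshold: 0.25
#' @export
item_information <- function(theta, thresholds) {
  if (any(!is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  pcm_moments(theta, thresholds)$var
}

#' Test information function
#'
#' Sum of [item_information()] over the items of an instrument.
#'
#' @param theta Numeric vector of person locations (logits).
#' @param ip An [item_parameters] object (or a plain list of threshold
#'   vectors).
#' @param items Optional item subset (ids or indices); default all items.
#' @return Numeric vector of test information at each `theta`.
#' @export
test_information <- function(theta, ip, items = NULL) {
  thr <- get_thresholds(ip, items)
  Reduce(`+`, lapply(thr, function(d) item_information(theta, d)))
}

#' Expected raw sum score
#'
#' Model-implied expected sum score `sum_i E[X_i | theta]` over an item
#' subset; a strictly increasing, continuous function of `theta` used to
#' build ordinal-to-interval conversion tables.
#'
#' @inheritParams test_information
#' @return Numeric vector of expected scores, same length as `theta`.
#' @export
expected_score <- function(theta, ip, items = NULL) {
  thr <- get_thresholds(ip, items)
  if (length(thr) == 0L) stop("empty item subset", call. = FALSE)
  if (any(!is.finite(theta))) stop("`theta` must be finite", call. = FALSE)
  Reduce(`+`, lapply(thr, function(d) pcm_moments(theta, d)$mean))
}

# Sum of mean/var/mu3 over items at a single theta (used by person estimation).
score_moments <- function(theta, thr_list) {
  mn <- v <- m3 <- 0
  for (d in thr_list) {
    mo <- pcm_moments(theta, d)
    mn <- mn + mo$mean; v <- v + mo$var; m3 <- m3 + mo$mu3
  }
  list(mean = mn, var = v, mu3 = m3)
}

# Resolve a threshold list from item_parameters or a raw list.
get_thresholds <- function(ip, items = NULL) {
  thr <- if (inherits(ip, "item_parameters")) ip$thresholds
         else if (is.list(ip)) ip
         else stop("`ip` must be an item_parameters object or a list of threshold vectors",
                   call. = FALSE)
  if (is.null(items)) return(thr)
  if (is.character(items)) {
    missing_ids <- setdiff(items, names(thr))
    if (length(missing_ids))
      stop("items not present in the parameter set: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    thr[items]
  } else thr[items]
}
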