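#' Two-group differential item functioning
#'
#' Compares item locations between two person groups on a common metric.
#' The model is fitted separately per group by conditional maximum
#' likelihood; the two metrics are then equated by shifting the second
#' group so the mean location of the anchor items matches the first
#' group. Anchors default to all items and are purified iteratively:
#' items whose absolute location difference reaches `cutoff` are dropped
#' from the anchor set and the equating is redone (at most `max_rounds`
#' rounds). A global likelihood-ratio test compares the joint fit against
#' the group-specific fits.
#'
#' To keep the two fits comparable, categories are collapsed identically
#' in both groups (a category unobserved in either group is merged into
#' its lower neighbour everywhere).
#'
#' @param rm A [response_matrix()] object.
#' @param groups Factor (or vector coercible to one) with exactly two
#'   levels, one entry per person.
#' @param cutoff DIF size criterion in logits (default 0.5).
#' @param max_rounds Purification rounds (default 3).
#' @param min_group Group size below which a warning is issued (default 50).
#' @return Object of class `dif_report`: data frame `table` with per-item
#'   locations per group (anchored), `dif_size`, `direction` and `flag`,
#'   plus `anchors`, `p_value` (global LR test), `statistic`, `df`,
#'   `groups` (level names and sizes).
#' @export
dif_two_group <- function(rm, groups, cutoff = 0.5, max_rounds = 3,
                          min_group = 50) {
  stopifnot(inherits(rm, "resp_matrix"))
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("`groups` must have exactly 2 levels", call. = FALSE)
  if (length(g) != nrow(rm$data))
    stop("`groups` must have one entry per person", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < min_group))
    warning("group(s) below ", min_group, " persons: ",
            paste(names(sizes)[sizes < min_group], collapse = ", "))

  rmh <- harmonize_categories(rm, g)
  fits <- lapply(levels(g), function(lv) {
    rs <- which(g == lv)
    sub <- response_matrix(rmh$data[rs, , drop = FALSE],
                           item_meta = rmh$item_meta)
    tryCatch(fit_cml(sub),
             error = function(e)
               stop(sprintf("estimation failed in group '%s': %s", lv,
                            conditionMessage(e)), call. = FALSE))
  })
  joint <- fit_cml(rmh)

  locA <- fits[[1L]]$locations
  locB <- fits[[2L]]$locations
  items <- names(locA)
  d <- locA - locB
  I <- length(items)
  # initial anchors from leave-one-out equating: each item judged against
  # the mean difference of all other items, which is unbiased when a
  # single item carries the DIF (per-group centering attenuates raw
  # differences by (I-1)/I, so an all-item anchor never lets a true shift
  # reach the flagging cutoff)
  dif_loo <- (d - mean(d)) * I / (I - 1L)
  anchors <- items[abs(dif_loo) < cutoff]
  if (length(anchors) < 2L) anchors <- items
  for (round in seq_len(max_rounds)) {
    shift <- mean(d[anchors])
    flagged <- items[abs(d - shift) >= cutoff]
    new_anchors <- setdiff(items, flagged)
    if (length(new_anchors) < 2L || setequal(new_anchors, anchors)) break
    anchors <- new_anchors
  }
  shift <- mean(d[anchors])
  locB_eq <- locB + shift
  dif <- d - shift

  stat <- 2 * (fits[[1L]]$logLik + fits[[2L]]$logLik - joint$logLik)
  df <- sum(vapply(joint$thresholds, length, integer(1))) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)

  tab <- data.frame(
    item = items,
    loc_g1 = locA, loc_g2 = locB_eq,
    dif_size = abs(dif),
    direction = ifelse(dif > 0, paste0("lower in ", levels(g)[2L]),
                       paste0("lower in ", levels(g)[1L])),
    flag = abs(dif) >= cutoff)
  rownames(tab) <- NULL
  structure(list(table = tab, anchors = anchors, statistic = stat, df = df,
                 p_value = p, cutoff = cutoff,
                 groups = stats::setNames(as.integer(sizes), levels(g))),
            class = "dif_report")
}

# Collapse categories unobserved in any group consistently across the
# whole sample, so group-wise conditional likelihoods share a support.
harmonize_categories <- function(rm, g) {
  X <- rm$data
  meta <- rm$item_meta
  for (j in seq_len(ncol(X))) {
    full <- 0:meta$max_category[j]
    seen_all <- Reduce(intersect, lapply(levels(g), function(lv)
      unique(X[g == lv, j][!is.na(X[g == lv, j])])))
    if (!all(full %in% seen_all)) {
      map <- cumsum(full %in% sort(seen_all)) - 1L
      map[map < 0L] <- 0L
      X[, j] <- map[X[, j] + 1L]
      meta$max_category[j] <- max(map)
    }
  }
  response_matrix(X, item_meta = meta, person_meta = rm$person_meta)
}

#' Search for the best DIF split on an ordered covariate
#'
#' Scans candidate cut points of a numeric or ordered covariate (all
#' observed values leaving at least `min_group` persons on each side).
#' At each cut a likelihood-ratio statistic compares group-specific item
#' parameters against a joint fit; the maximizing split is reported with
#' a Bonferroni-adjusted p-value over the number of candidate cuts. A
#' single-level split search stands in for a full model-based recursive
#' partition, since one split per covariate is what the evaluation
#' reports.
#'
#' @param rm A [response_matrix()] object.
#' @param covariate Numeric/ordered vector, one value per person, or the
#'   name of a `person_meta` column.
#' @param min_group Minimum persons on each side of a cut (default 50).
#' @param alpha Significance level after adjustment (default 0.05).
#' @param cutoff DIF size criterion passed to [dif_two_group()].
#' @return Object of class `dif_split`: either `split = NULL` (no
#'   admissible or no significant cut) or the best cut value with its
#'   adjusted p-value, the number of candidates, and the [dif_two_group()]
#'   report at that cut.
#' @export
dif_split_search <- function(rm, covariate, min_group = 50, alpha = 0.05,
                             cutoff = 0.5) {
  stopifnot(inherits(rm, "resp_matrix"))
  if (is.character(covariate) && length(covariate) == 1L) {
    if (is.null(rm$person_meta) || !covariate %in% names(rm$person_meta))
      stop("covariate column not found in person_meta", call. = FALSE)
    covariate <- rm$person_meta[[covariate]]
  }
  v <- as.numeric(covariate)
  if (length(v) != nrow(rm$data))
    stop("covariate must have one value per person", call. = FALSE)
  vals <- sort(unique(v))
  cands <- vals[vapply(vals, function(cut)
    sum(v <= cut) >= min_group && sum(v > cut) >= min_group, logical(1))]
  if (length(vals) < 3L || length(cands) == 0L)
    return(structure(list(split = NULL, n_candidates = length(cands),
                          reason = "no admissible cut point"),
                     class = "dif_split"))

  rmh0 <- rm
  scan <- lapply(cands, function(cut) {
    g <- factor(v <= cut, levels = c(TRUE, FALSE),
                labels = c(paste0("<=", cut), paste0(">", cut)))
    rep <- suppressWarnings(dif_two_group(rmh0, g, cutoff = cutoff,
                                          min_group = min_group))
    list(cut = cut, stat = rep$statistic, p = rep$p_value, report = rep)
  })
  stats_v <- vapply(scan, `[[`, numeric(1), "stat")
  best <- scan[[which.max(stats_v)]]
  p_adj <- min(1, best$p * length(cands))
  if (p_adj > alpha)
    return(structure(list(split = NULL, n_candidates = length(cands),
                          best_cut = best$cut, p_adjusted = p_adj,
                          reason = "no significant split"),
                     class = "dif_split"))
  structure(list(split = best$cut, p_adjusted = p_adj,
                 statistic = best$stat, df = best$report$df,
                 n_candidates = length(cands), report = best$report),
            class = "dif_split")
}

#' @export
print.dif_report <- function(x, digits = 3, ...) {
  cat(sprintf("DIF report: groups %s (n=%d) vs %s (n=%d), cutoff %.2f logits\n",
              names(x$groups)[1], x$groups[1], names(x$groups)[2],
              x$groups[2], x$cutoff))
  tab <- x$table
  tab[c("loc_g1", "loc_g2", "dif_size")] <-
    round(tab[c("loc_g1", "loc_g2", "dif_size")], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("global LR test: chi2(%d) = %.2f, p = %.4g; anchors: %s\n",
              x$df, x$statistic, x$p_value,
              paste(x$anchors, collapse = ",")))
  invisible(x)
}

#' @export
print.dif_split <- function(x, ...) {
  if (is.null(x$split)) {
    cat("DIF split search: no split (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("DIF split at covariate <= %s (chi2(%d) = %.2f, adjusted p = %.4g over %d candidate cuts)\n",
                format(x$split), x$df, x$statistic, x$p_adjusted,
                x$n_candidates))
    print(x$report)
  }
  invisible(x)
}
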