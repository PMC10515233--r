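#' Conditional person separation index from test information
#'
#' Reliability-information relation `PSI = 1 - 1/TI`, clipped at zero
#' where test information drops below 1. At PSI 0.7 this corresponds to a
#' test information of 10/3 (about 3.33), and at PSI 0.8 to 5.0.
#'
#' @param ti Test information (numeric vector, >= 0).
#' @return Conditional person separation index in [0, 1).
#' @seealso [information_for_psi()] for the inverse.
#' @export
psi_from_information <- function(ti) {
  if (any(ti < 0, na.rm = TRUE)) stop("test information must be >= 0", call. = FALSE)
  pmax(0, 1 - 1 / ti)
}

#' Test information required for a target person separation index
#'
#' Numerically inverts [psi_from_information()]: the information level at
#' which the conditional person separation index reaches `psi`.
#'
#' @param psi Target PSI in [0, 1).
#' @return Test information value.
#' @export
information_for_psi <- function(psi) {
  stopifnot(all(psi >= 0 & psi < 1))
  vapply(psi, function(p)
    stats::uniroot(function(ti) psi_from_information(ti) - p,
                   interval = c(1 + 1e-9, 1e9), tol = 1e-12)$root,
    numeric(1))
}

#' Check threshold ordering per item
#'
#' Flags items whose step thresholds are not strictly increasing with
#' category order (disordered thresholds signal response-category
#' malfunction, e.g. a level that is never the most probable response).
#'
#' @param ip An `item_parameters` object (or list of threshold vectors).
#' @return Data frame with `item`, `disordered`, `pairs` (offending
#'   adjacent pairs as "k/k+1"), `max_gap` (largest backward step in
#'   logits, 0 if ordered).
#' @export
ordered_thresholds_check <- function(ip) {
  thr <- get_thresholds(ip)
  out <- lapply(names(thr), function(id) {
    d <- diff(thr[[id]])
    bad <- which(d < 0)
    data.frame(item = id, disordered = length(bad) > 0,
               pairs = if (length(bad)) paste(sprintf("%d/%d", bad, bad + 1L),
                                              collapse = ",") else "",
               max_gap = if (length(bad)) max(-d[bad]) else 0)
  })
  do.call(rbind, out)
}

#' Person-item targeting summary
#'
#' Means and standard deviations of the person location distribution and
#' of the item locations and step thresholds, all on the shared logit
#' scale, plus binned counts for a Wright-map style display.
#'
#' @param pe A `person_estimates` object.
#' @param ip An `item_parameters` object.
#' @param breaks Histogram breaks for the shared axis (default
#'   `seq(-6, 6, 0.5)`, extended to cover the data).
#' @return Object of class `targeting_summary` with `person_mean`,
#'   `person_sd`, `item_mean`, `item_sd`, `thresholds` (all step
#'   locations), and `bins` (data frame of bin mid, person count,
#'   threshold count).
#' @export
targeting_summary <- function(pe, ip, breaks = seq(-6, 6, by = 0.5)) {
  stopifnot(inherits(pe, "person_estimates"), inherits(ip, "item_parameters"))
  th <- pe$theta[is.finite(pe$theta)]
  steps <- unlist(ip$thresholds, use.names = FALSE)
  lo <- floor(min(c(th, steps, breaks)) * 2) / 2
  hi <- ceiling(max(c(th, steps, breaks)) * 2) / 2
  breaks <- seq(lo, hi, by = diff(breaks[1:2]))
  bins <- data.frame(
    mid = utils::head(breaks, -1L) + diff(breaks) / 2,
    persons = as.vector(table(cut(th, breaks, include.lowest = TRUE))),
    thresholds = as.vector(table(cut(steps, breaks, include.lowest = TRUE))))
  if (length(th) < 2L)
    warning("fewer than 2 finite person locations: SD undefined")
  structure(list(
    person_mean = mean(th),
    person_sd = if (length(th) > 1L) stats::sd(th) else NA_real_,
    item_mean = mean(ip$locations),
    item_sd = stats::sd(ip$locations),
    threshold_mean = mean(steps),
    threshold_sd = stats::sd(steps),
    thresholds = steps, bins = bins),
    class = "targeting_summary")
}

#' Conditional reliability profile
#'
#' Test information over a grid of person locations, the conditional
#' person separation index `PSI = 1 - 1/TI`, the interval(s) where PSI
#' reaches `psi_threshold` (endpoints linearly interpolated between grid
#' points), and -- when person estimates are supplied -- the percentages
#' of persons below, inside and above that range, plus the percentages
#' beyond the most extreme item thresholds.
#'
#' @param ip An `item_parameters` object.
#' @param pe Optional `person_estimates`; extreme-score persons enter via
#'   their (finite) WLE locations.
#' @param psi_threshold Target PSI (default 0.7).
#' @param grid Evaluation grid in logits (default `seq(-6, 6, 0.01)`,
#'   extended to span the person estimates).
#' @param items Optional item subset.
#' @return Object of class `rel_profile`: data frame `profile` (theta,
#'   tif, psi), `intervals` (matrix of lower/upper endpoints),
#'   `coverage` (percent below/inside/above, summing to 100) and
#'   `threshold_coverage` (percent above the highest and below the lowest
#'   step threshold), plus the settings.
#' @export
reliability_profile <- function(ip, pe = NULL, psi_threshold = 0.7,
                                grid = seq(-6, 6, by = 0.01), items = NULL) {
  thr <- get_thresholds(ip, items)
  if (!is.null(pe)) {
    th <- pe$theta[is.finite(pe$theta)]
    if (length(th) && (min(th) < min(grid) || max(th) > max(grid))) {
      by <- diff(grid[1:2])
      grid <- seq(floor(min(c(grid, th))), ceiling(max(c(grid, th))), by = by)
    }
  }
  tif <- Reduce(`+`, lapply(thr, function(d) item_information(grid, d)))
  psi <- psi_from_information(tif)
  above <- psi >= psi_threshold
  intervals <- interval_runs(grid, psi, psi_threshold, above)

  coverage <- threshold_cov <- NULL
  if (!is.null(pe)) {
    th <- pe$theta[is.finite(pe$theta)]
    if (nrow(intervals)) {
      lo <- intervals[1L, "lower"]; hi <- intervals[nrow(intervals), "upper"]
      below <- 100 * mean(th < lo)
      abv <- 100 * mean(th > hi)
      coverage <- c(below = below, inside = 100 - below - abv, above = abv)
    } else {
      # threshold never reached: no usable range, so nobody is inside
      coverage <- c(below = NA_real_, inside = 0, above = NA_real_)
    }
    steps <- unlist(thr, use.names = FALSE)
    threshold_cov <- c(above_max = 100 * mean(th > max(steps)),
                       below_min = 100 * mean(th < min(steps)),
                       max_threshold = max(steps),
                       min_threshold = min(steps))
  }
  structure(list(profile = data.frame(theta = grid, tif = tif, psi = psi),
                 intervals = intervals, coverage = coverage,
                 threshold_coverage = threshold_cov,
                 psi_threshold = psi_threshold),
            class = "rel_profile")
}

# Contiguous runs where `above` holds, with linearly interpolated
# endpoints at the threshold crossings.
interval_runs <- function(grid, psi, thr, above) {
  if (!any(above))
    return(matrix(numeric(0), 0L, 2L,
                  dimnames = list(NULL, c("lower", "upper"))))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  interp <- function(i0, i1) {
    # crossing between grid[i0] (below) and grid[i1] (above)
    if (i0 < 1L || i0 > length(grid)) return(grid[i1])
    p0 <- psi[i0]; p1 <- psi[i1]
    if (!is.finite(p0) || p1 == p0) return(grid[i1])
    grid[i0] + (thr - p0) / (p1 - p0) * (grid[i1] - grid[i0])
  }
  out <- t(apply(runs, 1L, function(rn) {
    lower <- if (rn[1L] == 1L) grid[1L] else interp(rn[1L] - 1L, rn[1L])
    upper <- if (rn[2L] == length(grid)) grid[length(grid)]
             else interp(rn[2L] + 1L, rn[2L])
    c(lower = lower, upper = upper)
  }))
  colnames(out) <- c("lower", "upper")
  out
}

#' @export
print.rel_profile <- function(x, ...) {
  cat(sprintf("Conditional reliability profile (PSI threshold %.2f, TIF %.2f)\n",
              x$psi_threshold, information_for_psi(x$psi_threshold)))
  if (nrow(x$intervals)) {
    for (i in seq_len(nrow(x$intervals)))
      cat(sprintf("PSI >= %.2f on [%.2f, %.2f] logits\n", x$psi_threshold,
                  x$intervals[i, 1L], x$intervals[i, 2L]))
  } else cat("PSI threshold never reached\n")
  if (!is.null(x$coverage))
    cat(sprintf("persons: %.1f%% below, %.1f%% inside, %.1f%% above\n",
                x$coverage["below"], x$coverage["inside"],
                x$coverage["above"]))
  if (!is.null(x$threshold_coverage))
    cat(sprintf("%.1f%% above highest threshold (%.2f), %.1f%% below lowest (%.2f)\n",
                x$threshold_coverage["above_max"],
                x$threshold_coverage["max_threshold"],
                x$threshold_coverage["below_min"],
                x$threshold_coverage["min_threshold"]))
  invisible(x)
}

#' @export
print.targeting_summary <- function(x, ...) {
  cat(sprintf("Targeting: persons M = %.2f (SD = %.2f); items M = %.2f (SD = %.2f)\n",
              x$person_mean, x$person_sd, x$item_mean, x$item_sd))
  cat(sprintf("step thresholds: M = %.2f (SD = %.2f), range [%.2f, %.2f]\n",
              x$threshold_mean, x$threshold_sd, min(x$thresholds),
              max(x$thresholds)))
  invisible(x)
}
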