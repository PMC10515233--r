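#' Wright map: person and threshold distributions on one logit axis
#'
#' @param ts A `targeting_summary` from [targeting_summary()].
#' @return A ggplot object; persons above the axis, item step thresholds
#'   mirrored below.
#' @export
plot_wright_map <- function(ts) {
  stopifnot(inherits(ts, "targeting_summary"))
  b <- ts$bins
  df <- rbind(data.frame(mid = b$mid, count = b$persons, what = "persons"),
              data.frame(mid = b$mid, count = -b$thresholds,
                         what = "item thresholds"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count,
                                   fill = .data$what)) +
    ggplot2::geom_col(width = diff(b$mid[1:2]) * 0.9) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Location (logits)", y = "Count", fill = NULL,
                  title = "Person-item targeting") +
    ggplot2::theme_minimal()
}

#' Test information / conditional reliability curve
#'
#' @param profile A `rel_profile` from [reliability_profile()].
#' @param what `"tif"` or `"psi"`.
#' @return A ggplot object with the PSI-threshold band marked.
#' @export
plot_reliability <- function(profile, what = c("tif", "psi")) {
  stopifnot(inherits(profile, "rel_profile"))
  what <- match.arg(what)
  df <- profile$profile
  y <- if (what == "tif") df$tif else df$psi
  hline <- if (what == "tif") information_for_psi(profile$psi_threshold)
           else profile$psi_threshold
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = y)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = hline, linetype = 2) +
    ggplot2::labs(x = "Location (logits)",
                  y = if (what == "tif") "Test information"
                      else "Person separation index",
                  title = "Conditional reliability") +
    ggplot2::theme_minimal()
  if (nrow(profile$intervals))
    p <- p + ggplot2::annotate("rect",
                               xmin = profile$intervals[1, 1],
                               xmax = profile$intervals[1, 2],
                               ymin = -Inf, ymax = Inf, alpha = 0.1)
  p
}

#' Item location vs first-contrast loading
#'
#' The classic display behind a two-cluster diagnosis: items plotted by
#' their location and their loading on the first residual contrast.
#'
#' @param report A `dim_report` from [dimensionality_report()].
#' @return A ggplot object.
#' @export
plot_first_contrast <- function(report) {
  stopifnot(inherits(report, "dim_report"))
  df <- data.frame(item = names(report$loadings),
                   location = report$locations,
                   loading = report$loadings)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$location, y = .data$loading,
                                   label = .data$item)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_text() +
    ggplot2::labs(x = "Item location (logits)",
                  y = "Loading on first residual contrast",
                  title = "Residual structure") +
    ggplot2::theme_minimal()
}
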