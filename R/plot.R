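#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an average partition profile around initiation zones
#'
#' Draws the mean partition per signed offset from the IZ midpoint. A mark
#' co-segregating with the leading strand shows an S-shaped antisymmetric
#' curve through zero at the midpoint; a symmetric mark is flat at zero.
#'
#' @param object A `scar_metaprofile` from [metaprofile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scar_metaprofile
#' @export
autoplot.scar_metaprofile <- function(object, ...) {
  bw <- attr(object, "bin_width") %||% 1000
  df <- as_tibble(object)
  df$dist_kb <- df$offset * bw / 1000
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dist_kb, y = .data$mean_partition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(
      x = "Distance from IZ midpoint (kb)",
      y = "Mean partition (F - R)/(F + R)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.scar_metaprofile
#' @param profile A `scar_metaprofile`.
#' @export
plot_metaprofile <- function(profile, ...) {
  autoplot.scar_metaprofile(profile, ...)
}

#' Box plot of pooled oriented partition for one or more conditions
#'
#' Mirrors the pooled-window presentation: the box spans the first and third
#' quartiles of oriented partition (upstream windows multiplied by -1), the
#' line marks the median, whiskers extend to 1.5x the interquartile range.
#' The IZ-midpoint bin (offset 0) is excluded.
#'
#' @param ... Named `oriented_windows` tibbles (names become condition
#'   labels).
#' @return A ggplot object.
#' @export
plot_partition_boxplot <- function(...) {
  tables <- list(...)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("condition_", seq_along(tables))
  }
  df <- purrr::imap_dfr(tables, function(tb, nm) {
    tb <- tb[tb$offset != 0, ]
    tibble(condition = nm, partition_oriented = tb$partition_oriented)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$partition_oriented)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "#d1e5f0") +
    ggplot2::labs(x = NULL, y = "Oriented partition") +
    ggplot2::theme_minimal()
}
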