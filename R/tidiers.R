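#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired partition comparison
#'
#' @param x A `partition_test` from [pooled_partition_stats()].
#' @param ... Unused.
#' @return A tibble with one row per condition: `condition`, `median`, `q1`,
#'   `q3`, `n`.
#' @method tidy partition_test
#' @export
tidy.partition_test <- function(x, ...) {
  tibble(
    condition = c("a", "b"),
    median = c(x$median_a, x$median_b),
    q1 = c(x$q1_a, x$q1_b),
    q3 = c(x$q3_a, x$q3_b),
    n = x$n
  )
}

#' @rdname tidy.partition_test
#' @return For `glance`: a one-row tibble with `n`, `p.value`, `method`.
#' @method glance partition_test
#' @export
glance.partition_test <- function(x, ...) {
  tibble(n = x$n, p.value = x$p_value, method = x$method)
}

#' Tidy a leading-strand fraction estimate
#'
#' @param x A `leading_fraction` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate` (percent), `conf.low`,
#'   `conf.high`, `mean.partition`, `n.windows`, `n.iz`.
#' @method tidy leading_fraction
#' @export
tidy.leading_fraction <- function(x, ...) {
  tibble(
    estimate = x$estimate,
    conf.low = x$conf_low,
    conf.high = x$conf_high,
    mean.partition = x$mean_partition,
    n.windows = x$n_windows,
    n.iz = x$n_iz
  )
}

#' @rdname tidy.leading_fraction
#' @method glance leading_fraction
#' @export
glance.leading_fraction <- function(x, ...) {
  tidy.leading_fraction(x)
}
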