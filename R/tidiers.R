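#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the permutation overlap distributions
#'
#' @param x A `scase_ma_permutation` from
#'   [between_vs_within_permutation()].
#' @param ... Unused.
#' @return A tibble with one row per draw: `iteration, comparison`
#'   (`"within"`/`"between"`), `overlap`.
#' @export
tidy.scase_ma_permutation <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(iteration = seq_along(x$within), comparison = "within",
                   overlap = x$within),
    tibble::tibble(iteration = seq_along(x$between), comparison = "between",
                   overlap = x$between)
  )
}

#' One-row summary of a permutation test
#'
#' @param x A `scase_ma_permutation`.
#' @param ... Unused.
#' @return A one-row tibble with the compared types, group size `k`, mean
#'   overlaps, t-statistic and p-value.
#' @export
glance.scase_ma_permutation <- function(x, ...) {
  tibble::tibble(
    type_a = x$type_a, type_b = x$type_b, k = x$k, n_iter = x$n_iter,
    mean_within = mean(x$within), mean_between = mean(x$between),
    t_statistic = x$t_statistic, p_value = x$p_value
  )
}

#' @export
print.scase_ma_permutation <- function(x, ...) {
  cat(sprintf("<MA overlap permutation: %s within vs %s between, k = %d>\n",
              x$type_a, x$type_b, x$k))
  cat(sprintf("  mean within %.2f, mean between %.2f, t = %.2f, p = %.3g\n",
              mean(x$within), mean(x$between), x$t_statistic, x$p_value))
  invisible(x)
}

#' Tidy an imprinted-gene ratio check
#'
#' @param x A `scase_imprinted_check` from [imprinted_ratio_check()].
#' @param ... Unused.
#' @return The per-site observation tibble with deviations and flags.
#' @export
tidy.scase_imprinted_check <- function(x, ...) {
  tibble::as_tibble(x$observations)
}

#' @rdname tidy.scase_imprinted_check
#' @return For `glance()`, the per-group test summary tibble.
#' @export
glance.scase_imprinted_check <- function(x, ...) {
  x$tests
}
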