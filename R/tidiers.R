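#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated experiment
#'
#' @param x A [run_experiment()] result.
#' @param ... Unused.
#' @return The pooled fragmentation-event tibble, one row per MS2 event.
#' @export
tidy.dda_experiment <- function(x, ...) {
  dplyr::mutate(x$events, strategy = x$cfg$strategy, .before = 1)
}

#' @rdname tidy.dda_experiment
#' @return For `glance()`: a one-row tibble with the strategy, injection
#'   and scan counts.
#' @export
glance.dda_experiment <- function(x, ...) {
  tibble::tibble(
    strategy = x$cfg$strategy,
    n_injections = nrow(x$injections),
    n_ms1 = sum(x$injections$n_ms1),
    n_ms2 = sum(x$injections$n_ms2),
    n_carried_windows = length(x$registry$car$rt_lo)
  )
}

#' Tidy a coverage report
#'
#' @param x A [coverage()] report.
#' @param ... Unused.
#' @return The per-injection tibble (`injection`, `n_covered`,
#'   `coverage`, `intensity_coverage`).
#' @export
tidy.coverage_report <- function(x, ...) x$by_injection

#' @rdname tidy.coverage_report
#' @return For `glance()`: a one-row tibble with the final cumulative
#'   metrics.
#' @export
glance.coverage_report <- function(x, ...) {
  n <- nrow(x$by_injection)
  tibble::tibble(
    n_rows = x$n_rows,
    n_injections = n,
    coverage = if (n) x$by_injection$coverage[n] else 0,
    intensity_coverage = if (n) x$by_injection$intensity_coverage[n] else 0
  )
}

#' Plot cumulative coverage curves
#'
#' Per-injection cumulative peak coverage and intensity coverage, the two
#' panels used to compare fragmentation strategies.
#'
#' @param object A [coverage()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$by_injection,
                            c("coverage", "intensity_coverage"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$injection, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "injection", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot several strategies' coverage curves together
#'
#' @param reports Named list of [coverage()] reports sharing a peaklist.
#' @param metric `"coverage"`, `"intensity_coverage"`, or both.
#' @return A ggplot.
#' @export
plot_strategy_comparison <- function(reports,
                                     metric = c("coverage",
                                                "intensity_coverage")) {
  metric <- match.arg(metric, several.ok = TRUE)
  df <- purrr::imap(reports, function(r, nm) {
    dplyr::mutate(r$by_injection, strategy = nm)
  }) |> dplyr::bind_rows()
  df <- tidyr::pivot_longer(df, dplyr::all_of(metric),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$injection, .data$value,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "injection", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}
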