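#' Cumulative coverage of fragmentation events against an aligned peaklist
#'
#' The package's two headline metrics, computed per injection against a
#' set of aligned picked peaks. A peak row is covered after injection `k`
#' if any fragmentation event in injections `1..k`, acquired in a sample
#' where the row has a box, falls inside that box (closed intervals).
#' Peak coverage is the fraction of rows covered. Intensity coverage is
#' the summed best matched precursor intensity per row -- 0 while
#' uncovered, capped at the row's apex intensity -- divided by the summed
#' row apex intensities; it is a proxy for spectral quality and reaches 1
#' only when every row has been acquired at (or above) its apex.
#'
#' A row present in several samples is covered by a matching event in any
#' of them; its apex intensity is the maximum over its per-sample boxes.
#'
#' @param events Event tibble with columns `injection`, `sample`, `rt`,
#'   `precursor_mz`, `precursor_intensity` (as produced by
#'   [run_experiment()]).
#' @param peaks Aligned peaklist tibble: `row_id`, `sample`, `rt_lo`,
#'   `rt_hi`, `mz_lo`, `mz_hi`, `apex_intensity` (e.g. a cohort's
#'   `truth_peaks` or [read_peaklist()] output).
#' @param n_injections Report length; defaults to the largest injection
#'   index in `events`.
#' @return A list of class `coverage_report`: `by_injection` (tibble:
#'   `injection`, `n_covered`, `coverage`, `intensity_coverage`),
#'   `per_peak` (tibble: `row_id`, `apex_intensity`, `best_intensity`,
#'   `first_injection`), `n_rows`.
#' @export
coverage <- function(events, peaks, n_injections = NULL) {
  if (inherits(events, "dda_experiment")) {
    if (is.null(n_injections)) n_injections <- nrow(events$injections)
    events <- events$events
  }
  req <- c("row_id", "sample", "rt_lo", "rt_hi", "mz_lo", "mz_hi",
           "apex_intensity")
  if (!all(req %in% names(peaks))) {
    stop("peaklist lacks columns: ",
         paste(setdiff(req, names(peaks)), collapse = ", "), call. = FALSE)
  }
  if (nrow(events) && !all(events$sample %in% peaks$sample)) {
    bad <- setdiff(unique(events$sample), unique(peaks$sample))
    stop("events reference unknown sample id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows <- peaks |>
    dplyr::group_by(.data$row_id) |>
    dplyr::summarise(apex_intensity = max(.data$apex_intensity),
                     .groups = "drop")
  n_rows <- nrow(rows)
  denom <- sum(rows$apex_intensity)
  if (is.null(n_injections)) {
    n_injections <- if (nrow(events)) max(events$injection) else 0L
  }

  matches <- match_events_to_peaks(events, peaks)
  by_inj <- vector("list", n_injections)
  best <- stats::setNames(rep(0, n_rows), rows$row_id)
  first_inj <- stats::setNames(rep(NA_integer_, n_rows), rows$row_id)
  for (k in seq_len(n_injections)) {
    mk <- matches[matches$injection == k, , drop = FALSE]
    if (nrow(mk)) {
      upd <- tapply(mk$matched_intensity, mk$row_id, max)
      ids <- names(upd)
      newly <- ids[is.na(first_inj[ids])]
      first_inj[newly] <- k
      best[ids] <- pmax(best[ids], unname(upd))
    }
    by_inj[[k]] <- tibble::tibble(
      injection = k,
      n_covered = sum(!is.na(first_inj)),
      coverage = if (n_rows) sum(!is.na(first_inj)) / n_rows else 0,
      intensity_coverage = if (denom > 0) sum(best) / denom else 0
    )
  }
  structure(list(
    by_injection = dplyr::bind_rows(by_inj),
    per_peak = tibble::tibble(row_id = rows$row_id,
                              apex_intensity = rows$apex_intensity,
                              best_intensity = unname(best),
                              first_injection = unname(first_inj)),
    n_rows = n_rows
  ), class = "coverage_report")
}

# events x peaks containment join. Peak m/z boxes are narrow, so slice by
# sorted mz_lo per sample; matched intensity is capped at the box apex.
match_events_to_peaks <- function(events, peaks) {
  out <- list()
  for (s in unique(events$sample)) {
    es <- events[events$sample == s, , drop = FALSE]
    ps <- peaks[peaks$sample == s, , drop = FALSE]
    if (!nrow(es) || !nrow(ps)) next
    o <- order(ps$mz_lo)
    ps <- ps[o, ]
    wmax <- max(ps$mz_hi - ps$mz_lo)
    lo <- findInterval(es$precursor_mz - wmax, ps$mz_lo, left.open = TRUE) + 1L
    hi <- findInterval(es$precursor_mz, ps$mz_lo)
    for (i in seq_len(nrow(es))) {
      if (hi[i] < lo[i]) next
      sl <- seq.int(lo[i], hi[i])
      hit <- sl[es$precursor_mz[i] >= ps$mz_lo[sl] &
                es$precursor_mz[i] <= ps$mz_hi[sl] &
                es$rt[i] >= ps$rt_lo[sl] & es$rt[i] <= ps$rt_hi[sl]]
      if (length(hit)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          injection = es$injection[i],
          row_id = ps$row_id[hit],
          matched_intensity = pmin(es$precursor_intensity[i],
                                   ps$apex_intensity[hit]))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(injection = integer(), row_id = character(),
                          matched_intensity = numeric()))
  }
  dplyr::bind_rows(out)
}

#' @export
print.coverage_report <- function(x, ...) {
  n <- nrow(x$by_injection)
  cat("<coverage_report> ", x$n_rows, " peak rows, ", n, " injection(s)\n",
      sep = "")
  if (n) {
    cat(sprintf("  final coverage %.3f, intensity coverage %.3f\n",
                x$by_injection$coverage[n],
                x$by_injection$intensity_coverage[n]))
  }
  invisible(x)
}

#' Compare coverage reports across strategies
#'
#' Stacks per-injection curves from several reports (which must share the
#' peaklist and injection count) and adds per-injection differences from a
#' baseline strategy.
#'
#' @param reports Named list of [coverage()] reports; the first (or
#'   `baseline`) is the reference.
#' @param baseline Name of the reference report.
#' @return A tibble: `injection`, `strategy`, `coverage`,
#'   `intensity_coverage`, `d_coverage`, `d_intensity_coverage` (deltas
#'   vs the baseline at the same injection). Final-injection deltas are in
#'   attribute `"final"`.
#' @export
compare_strategies <- function(reports, baseline = names(reports)[1]) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)),
            baseline %in% names(reports))
  n_inj <- unique(vapply(reports, function(r) nrow(r$by_injection),
                         integer(1)))
  if (length(n_inj) != 1) {
    stop("reports have mismatched injection counts", call. = FALSE)
  }
  n_rows <- unique(vapply(reports, `[[`, integer(1), "n_rows"))
  if (length(n_rows) != 1) {
    stop("reports were computed against different peaklists", call. = FALSE)
  }
  long <- purrr::imap(reports, function(r, nm) {
    dplyr::mutate(r$by_injection, strategy = nm, .before = 1)
  }) |> dplyr::bind_rows()
  base <- reports[[baseline]]$by_injection
  long <- long |>
    dplyr::mutate(
      d_coverage = .data$coverage -
        base$coverage[match(.data$injection, base$injection)],
      d_intensity_coverage = .data$intensity_coverage -
        base$intensity_coverage[match(.data$injection, base$injection)]
    ) |>
    dplyr::select("injection", "strategy", "coverage",
                  "intensity_coverage", "d_coverage",
                  "d_intensity_coverage")
  fin <- long[long$injection == n_inj, , drop = FALSE]
  attr(long, "final") <- fin
  long
}
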