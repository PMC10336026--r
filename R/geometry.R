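#' Axis-aligned rectangles in (retention time, m/z) space
#'
#' A `rect` is the geometric unit shared by regions of interest (RoIs),
#' dynamic exclusion windows, and picked-peak boxes: an axis-aligned box
#' with retention-time bounds in seconds and m/z bounds in Daltons.
#' `rect()` builds a validated tibble of rectangles (one row each).
#'
#' Intervals are closed; two rectangles that merely touch along an edge
#' share zero area and are treated as non-overlapping by every area-based
#' score in the package.
#'
#' @param rt_lo,rt_hi Retention-time bounds (seconds), `rt_lo <= rt_hi`.
#' @param mz_lo,mz_hi m/z bounds (Daltons), `mz_lo <= mz_hi`.
#' @param id Optional character identifiers (must be unique if given).
#' @return A tibble with columns `id` (if given), `rt_lo`, `rt_hi`,
#'   `mz_lo`, `mz_hi`.
#' @examples
#' rect(0, 2, 0, 2)
#' rect_area(rect(c(0, 1), c(2, 3), c(0, 1), c(2, 3)))
#' @export
rect <- function(rt_lo, rt_hi, mz_lo, mz_hi, id = NULL) {
  n <- max(length(rt_lo), length(rt_hi), length(mz_lo), length(mz_hi))
  out <- tibble::tibble(
    rt_lo = rep_len(as.numeric(rt_lo), n),
    rt_hi = rep_len(as.numeric(rt_hi), n),
    mz_lo = rep_len(as.numeric(mz_lo), n),
    mz_hi = rep_len(as.numeric(mz_hi), n)
  )
  if (!is.null(id)) {
    if (anyDuplicated(id)) stop("rect ids must be unique", call. = FALSE)
    out <- tibble::add_column(out, id = as.character(id), .before = 1)
  }
  if (any(out$rt_lo > out$rt_hi) || any(out$mz_lo > out$mz_hi)) {
    stop("invalid rect: need rt_lo <= rt_hi and mz_lo <= mz_hi", call. = FALSE)
  }
  out
}

#' @rdname rect
#' @param rects A tibble of rectangles as returned by [rect()].
#' @export
rect_area <- function(rects) {
  (rects$rt_hi - rects$rt_lo) * (rects$mz_hi - rects$mz_lo)
}

# Core dissection on plain numeric vectors. Clips the covering boxes to the
# query, cuts the query along every boundary into grid cells, and labels each
# cell with the exact subset of boxes covering it (bitmask for <= 50 boxes,
# key string beyond). Cell edges coincide with box edges, so a cell-centre
# test decides coverage exactly; zero-width strips are dropped, which is what
# makes boundary-touching rectangles count as non-overlapping.
#
# Returns list(degenerate, area, keys, areas, members) where `members` is a
# list of integer vectors indexing the input boxes (empty = uncovered).
dissect_core <- function(q_rt_lo, q_rt_hi, q_mz_lo, q_mz_hi,
                         b_rt_lo, b_rt_hi, b_mz_lo, b_mz_hi) {
  area_q <- (q_rt_hi - q_rt_lo) * (q_mz_hi - q_mz_lo)
  k <- length(b_rt_lo)
  if (k) {
    keep <- b_rt_lo <= q_rt_hi & b_rt_hi >= q_rt_lo &
      b_mz_lo <= q_mz_hi & b_mz_hi >= q_mz_lo
    b_rt_lo <- b_rt_lo[keep]; b_rt_hi <- b_rt_hi[keep]
    b_mz_lo <- b_mz_lo[keep]; b_mz_hi <- b_mz_hi[keep]
    idx <- which(keep)
    k <- length(idx)
  } else idx <- integer()
  if (area_q <= 0) {
    # degenerate query: still report which boxes contain the point/segment
    inside <- if (k) {
      b_rt_lo <= q_rt_lo & b_rt_hi >= q_rt_hi &
        b_mz_lo <= q_mz_lo & b_mz_hi >= q_mz_hi
    } else logical()
    return(list(degenerate = TRUE, area = 0,
                keys = "deg", areas = 0,
                members = list(idx[inside])))
  }
  if (k == 0L) {
    return(list(degenerate = FALSE, area = area_q,
                keys = "0", areas = area_q, members = list(integer())))
  }
  rt_cuts <- sort(unique(c(q_rt_lo, q_rt_hi,
                           pmin(pmax(b_rt_lo, q_rt_lo), q_rt_hi),
                           pmin(pmax(b_rt_hi, q_rt_lo), q_rt_hi))))
  mz_cuts <- sort(unique(c(q_mz_lo, q_mz_hi,
                           pmin(pmax(b_mz_lo, q_mz_lo), q_mz_hi),
                           pmin(pmax(b_mz_hi, q_mz_lo), q_mz_hi))))
  d_rt <- diff(rt_cuts); d_mz <- diff(mz_cuts)
  pos_rt <- d_rt > 0; pos_mz <- d_mz > 0
  rt_c <- (rt_cuts[-1] + rt_cuts[-length(rt_cuts)])[pos_rt] / 2
  mz_c <- (mz_cuts[-1] + mz_cuts[-length(mz_cuts)])[pos_mz] / 2
  d_rt <- d_rt[pos_rt]; d_mz <- d_mz[pos_mz]
  nr <- length(rt_c); nm <- length(mz_c)
  # coverage per cell, combination key per cell
  if (k <= 50L) {
    key <- matrix(0, nr, nm)
    for (j in seq_len(k)) {
      cov <- outer(rt_c >= b_rt_lo[j] & rt_c <= b_rt_hi[j],
                   mz_c >= b_mz_lo[j] & mz_c <= b_mz_hi[j], `&`)
      key <- key + cov * 2^(j - 1)
    }
    cell_area <- outer(d_rt, d_mz)
    areas <- rowsum(as.vector(cell_area), as.vector(key))
    key_vals <- as.numeric(rownames(areas))
    members <- lapply(key_vals, function(v) {
      out <- integer()
      for (j in seq_len(k)) if (v %/% 2^(j - 1) %% 2 >= 1) out <- c(out, idx[j])
      out
    })
    list(degenerate = FALSE, area = area_q,
         keys = as.character(key_vals), areas = as.vector(areas),
         members = members)
  } else {
    covs <- vapply(seq_len(k), function(j) {
      as.vector(outer(rt_c >= b_rt_lo[j] & rt_c <= b_rt_hi[j],
                      mz_c >= b_mz_lo[j] & mz_c <= b_mz_hi[j], `&`))
    }, logical(nr * nm))
    keys <- apply(covs, 1L, function(z) paste(which(z), collapse = ","))
    cell_area <- as.vector(outer(d_rt, d_mz))
    areas <- rowsum(cell_area, keys)
    key_vals <- rownames(areas)
    members <- lapply(key_vals, function(s) {
      if (!nzchar(s)) integer() else idx[as.integer(strsplit(s, ",")[[1]])]
    })
    list(degenerate = FALSE, area = area_q,
         keys = key_vals, areas = as.vector(areas), members = members)
  }
}

#' Dissect a query rectangle against a set of covering rectangles
#'
#' Cuts the query rectangle into interior-disjoint pieces, each labelled with
#' the exact subset of covering rectangles ("owners") over it. Pieces with an
#' empty owner set are the query's area of non-overlap. Piece areas always
#' sum to the query area; zero-area pieces are omitted.
#'
#' This is the kernel behind the non-overlap and intensity non-overlap
#' scores: the former needs the uncovered fraction, the latter the area of
#' every distinct owner combination.
#'
#' @param query A one-row rectangle tibble ([rect()]).
#' @param others A rectangle tibble with an `id` column (may have zero rows).
#' @return A `dissection`: list with `pieces` (tibble `rt_lo`, `rt_hi`,
#'   `mz_lo`, `mz_hi` only for grid pieces of gridless cases, plus `area`
#'   and `owners`, a list-column of character id vectors), `query_area`,
#'   and `degenerate`. A zero-area query yields a single zero-area piece
#'   flagged degenerate; callers treat its non-overlap proportion as 1.
#' @examples
#' d <- dissect(rect(0, 2, 0, 2), rect(1, 3, 1, 3, id = "b"))
#' non_overlap_proportion(d)   # 0.75
#' @export
dissect <- function(query, others = rect(numeric(), numeric(), numeric(), numeric(), id = character())) {
  stopifnot(nrow(query) == 1L)
  if (nrow(others) && !"id" %in% names(others)) {
    stop("`others` must carry an `id` column", call. = FALSE)
  }
  core <- dissect_core(query$rt_lo, query$rt_hi, query$mz_lo, query$mz_hi,
                       others$rt_lo, others$rt_hi, others$mz_lo, others$mz_hi)
  owners <- lapply(core$members, function(ix) as.character(others$id[ix]))
  pieces <- tibble::tibble(area = core$areas, owners = owners)
  structure(
    list(pieces = pieces, query_area = core$area, degenerate = core$degenerate),
    class = "dissection"
  )
}

#' @export
print.dissection <- function(x, ...) {
  cat("<dissection> query area ", format(x$query_area),
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  df <- x$pieces
  df$owners <- vapply(df$owners, function(o) {
    if (!length(o)) "(none)" else paste(o, collapse = "+")
  }, character(1))
  print(df, ...)
  invisible(x)
}

#' Proportion of a dissected query left uncovered
#'
#' The area of the pieces owned by no covering rectangle, divided by the
#' query area: the `[0, 1]` weight the non-overlap score applies to the log
#' intensity. Degenerate (zero-area) queries return 1.
#'
#' @param d A [dissect()] result.
#' @return A number in `[0, 1]`.
#' @export
non_overlap_proportion <- function(d) {
  stopifnot(inherits(d, "dissection"))
  if (d$degenerate) return(1)
  empty <- !vapply(d$pieces$owners, length, integer(1))
  sum(d$pieces$area[empty]) / d$query_area
}

# Fast scalar form used by the controllers: uncovered fraction of a query
# rect against covering boxes, without building the dissection object.
non_overlap_prop_core <- function(q_rt_lo, q_rt_hi, q_mz_lo, q_mz_hi,
                                  b_rt_lo, b_rt_hi, b_mz_lo, b_mz_hi) {
  core <- dissect_core(q_rt_lo, q_rt_hi, q_mz_lo, q_mz_hi,
                       b_rt_lo, b_rt_hi, b_mz_lo, b_mz_hi)
  if (core$degenerate) return(1)
  empty <- !vapply(core$members, length, integer(1))
  sum(core$areas[empty]) / core$area
}

#' Intensity-weighted region sum over a dissection
#'
#' For each distinct owner combination `B` over the query, forms the
#' modified intensity `lambda_query - max(lambda over B)` (0 over the empty
#' combination), raises it to the combination's proportional area, and sums
#' the positive terms. This is the argument of the logarithm in the
#' intensity non-overlap score; with no covering boxes it reduces to the raw
#' query intensity.
#'
#' Combinations whose modified intensity is non-positive contribute 0 (a
#' negative base under a fractional exponent is undefined), and zero-area
#' combinations never appear (they would contribute a spurious
#' `lambda^0 = 1`).
#'
#' @param d A [dissect()] result.
#' @param lambda_query Query intensity (counts, `>= 0`).
#' @param lambda_others Named numeric vector of covering-box intensities,
#'   names matching the `others` ids passed to [dissect()].
#' @return A non-negative number (may be 0; callers map `<= 1` to score 0).
#' @examples
#' d <- dissect(rect(0, 2, 0, 2), rect(1, 3, 1, 3, id = "b"))
#' intensity_region_sum(d, 1000, c(b = 100))   # 1000^0.75 + 900^0.25
#' @export
intensity_region_sum <- function(d, lambda_query, lambda_others = numeric()) {
  stopifnot(inherits(d, "dissection"))
  if (length(lambda_others) && any(lambda_others < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  if (d$degenerate) {
    own <- d$pieces$owners[[1]]
    lam_max <- if (length(own)) max(lambda_others[own]) else 0
    return(max(0, lambda_query - lam_max))
  }
  terms <- vapply(seq_len(nrow(d$pieces)), function(i) {
    own <- d$pieces$owners[[i]]
    lam_max <- if (length(own)) max(lambda_others[own]) else 0
    lam_mod <- lambda_query - lam_max
    if (lam_mod <= 0) return(0)
    lam_mod^(d$pieces$area[i] / d$query_area)
  }, numeric(1))
  sum(terms)
}

# Scalar core form for the controllers: lambdas indexed parallel to boxes.
intensity_region_sum_core <- function(q_rt_lo, q_rt_hi, q_mz_lo, q_mz_hi,
                                      lambda_query,
                                      b_rt_lo, b_rt_hi, b_mz_lo, b_mz_hi,
                                      lambda_b) {
  core <- dissect_core(q_rt_lo, q_rt_hi, q_mz_lo, q_mz_hi,
                       b_rt_lo, b_rt_hi, b_mz_lo, b_mz_hi)
  if (core$degenerate) {
    ix <- core$members[[1]]
    lam_max <- if (length(ix)) max(lambda_b[ix]) else 0
    return(max(0, lambda_query - lam_max))
  }
  total <- 0
  for (i in seq_along(core$areas)) {
    ix <- core$members[[i]]
    lam_max <- if (length(ix)) max(lambda_b[ix]) else 0
    lam_mod <- lambda_query - lam_max
    if (lam_mod > 0) total <- total + lam_mod^(core$areas[i] / core$area)
  }
  total
}
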