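#' RoI-building parameters
#'
#' Controls the centwave-style linking of MS1 points into regions of
#' interest (RoIs): the m/z tolerance within which a point extends an
#' existing live RoI, the minimum intensity a point needs to start or
#' extend a RoI, and how many consecutive scans a RoI may miss before it
#' is closed.
#'
#' @param mz_tol m/z matching tolerance; ppm by default.
#' @param mz_tol_unit `"ppm"` (relative to the RoI's last point) or `"da"`.
#' @param min_intensity Minimum point intensity (counts) to start/extend.
#' @param max_missed RoIs receiving no point for more than this many scans
#'   are closed.
#' @param store_points Keep full point traces (needed for converting RoIs
#'   back into chemicals; off by default to keep acquisition runs light).
#' @return A list of class `roi_params`.
#' @export
roi_params <- function(mz_tol = 10, mz_tol_unit = c("ppm", "da"),
                       min_intensity = 500, max_missed = 2,
                       store_points = FALSE) {
  mz_tol_unit <- match.arg(mz_tol_unit)
  stopifnot(mz_tol > 0, min_intensity >= 0, max_missed >= 0)
  structure(list(mz_tol = mz_tol, mz_tol_unit = mz_tol_unit,
                 min_intensity = min_intensity, max_missed = max_missed,
                 store_points = isTRUE(store_points)),
            class = "roi_params")
}

#' Dynamic-exclusion configuration
#'
#' The within-injection refragmentation rule applied to RoIs after a
#' fragmentation event. `plain` forbids refragmentation for `rt_tol`
#' seconds. `weighteddew` ramps the weight linearly from 0 at `t0` seconds
#' after the event to 1 at `rt_tol`. `smartroi` re-enables refragmentation
#' when the RoI's intensity has risen by `intensity_increase_factor` over
#' the minimum seen since the event, when it drops below `drop_fraction`
#' of the intensity at fragmentation, or after `reset_length` seconds.
#'
#' @param scheme One of `"plain"`, `"smartroi"`, `"weighteddew"`.
#' @param rt_tol Exclusion duration (seconds).
#' @param t0 WeightedDEW ramp start (seconds), `0 <= t0 <= rt_tol`.
#' @param intensity_increase_factor SmartRoI re-enable factor (`>= 1`).
#' @param drop_fraction SmartRoI drop trigger, in `(0, 1]`.
#' @param reset_length SmartRoI time-based re-enable (seconds).
#' @return A list of class `dew_config`.
#' @export
dew_config <- function(scheme = c("plain", "smartroi", "weighteddew"),
                       rt_tol = 15, t0 = 3,
                       intensity_increase_factor = 10,
                       drop_fraction = 0.01, reset_length = 100) {
  scheme <- match.arg(scheme)
  stopifnot(rt_tol > 0, t0 >= 0, t0 <= rt_tol,
            intensity_increase_factor >= 1,
            drop_fraction > 0, drop_fraction <= 1, reset_length > 0)
  structure(list(scheme = scheme, rt_tol = rt_tol, t0 = t0,
                 intensity_increase_factor = intensity_increase_factor,
                 drop_fraction = drop_fraction, reset_length = reset_length),
            class = "dew_config")
}

#' Create an empty RoI store
#'
#' The mutable state the real-time tracker builds RoIs into: parallel
#' per-RoI vectors (bounds, last point, missed-scan count, fragmentation
#' history, SmartRoI bookkeeping), grown as scans arrive. Point traces are
#' kept only when the parameters request them.
#'
#' @param params A [roi_params()].
#' @return An empty `roi_state` environment.
#' @export
roi_state <- function(params = roi_params()) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$n <- 0L
  e$live <- logical()
  e$last_mz <- e$last_int <- e$last_rt <- numeric()
  e$rt_min <- e$rt_max <- e$mz_min <- e$mz_max <- numeric()
  e$missed <- integer()
  e$n_pts <- integer()
  e$last_frag_rt <- numeric()       # NA until fragmented
  e$frag_max_int <- numeric()       # max precursor intensity over events
  e$frag_n <- integer()
  e$sr_frag_int <- numeric()        # SmartRoI reference intensity
  e$sr_min_since <- numeric()
  e$pts <- list()                   # per-roi list(mz=, rt=, int=)
  class(e) <- "roi_state"
  e
}

roi_new_slot <- function(state, mz, intensity, rt) {
  i <- state$n + 1L
  state$n <- i
  state$live[i] <- TRUE
  state$last_mz[i] <- mz; state$last_int[i] <- intensity; state$last_rt[i] <- rt
  state$rt_min[i] <- rt; state$rt_max[i] <- rt
  state$mz_min[i] <- mz; state$mz_max[i] <- mz
  state$missed[i] <- 0L; state$n_pts[i] <- 1L
  state$last_frag_rt[i] <- NA_real_
  state$frag_max_int[i] <- 0; state$frag_n[i] <- 0L
  state$sr_frag_int[i] <- NA_real_; state$sr_min_since[i] <- NA_real_
  if (state$params$store_points) {
    state$pts[[i]] <- list(mz = mz, rt = rt, int = intensity)
  }
  i
}

#' Feed one MS1 scan to the RoI tracker
#'
#' Each scan point at or above the minimum intensity either extends the
#' nearest live RoI within the m/z tolerance or seeds a new one; no point
#' joins two RoIs, and a RoI accepts at most one point per scan (the
#' nearest; the displaced point seeds a new RoI). Live RoIs receiving no
#' point accrue a missed scan and are closed once they exceed the allowed
#' maximum. Ties (a point equidistant between two RoIs) go to the
#' lower-m/z RoI.
#'
#' @param state A [roi_state()] (modified in place and returned invisibly).
#' @param mz,intensity Scan point vectors, `mz` sorted ascending.
#' @param rt Scan retention time (seconds).
#' @return (Invisibly) a list with integer RoI indices `extended`, `opened`,
#'   `closed` for this scan.
#' @export
roi_update <- function(state, mz, intensity, rt) {
  stopifnot(inherits(state, "roi_state"))
  if (is.unsorted(mz)) stop("scan points must be sorted by mz", call. = FALSE)
  p <- state$params
  keep <- intensity >= p$min_intensity
  mz <- mz[keep]; intensity <- intensity[keep]
  live_idx <- which(state$live)
  extended <- integer(); opened <- integer()
  if (length(mz)) {
    if (length(live_idx)) {
      lm <- state$last_mz[live_idx]
      ord <- order(lm, live_idx)       # ties broken toward lower slot
      lm_s <- lm[ord]
      pos <- findInterval(mz, lm_s)
      lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(lm_s))
      d_lo <- abs(mz - lm_s[lo]); d_hi <- abs(lm_s[hi] - mz)
      # nearest live RoI; exact ties -> lower m/z (the `lo` side)
      pick <- ifelse(pos == 0L, hi, ifelse(pos >= length(lm_s), lo,
                     ifelse(d_lo <= d_hi, lo, hi)))
      dist <- abs(mz - lm_s[pick])
      tol <- if (p$mz_tol_unit == "ppm") lm_s[pick] * p$mz_tol * 1e-6 else p$mz_tol
      match_slot <- ifelse(dist <= tol, live_idx[ord][pick], NA_integer_)
      # one point per RoI per scan: on conflict keep the nearest point
      if (anyDuplicated(stats::na.omit(match_slot))) {
        o <- order(dist)
        seen <- integer()
        for (ii in o) {
          s <- match_slot[ii]
          if (!is.na(s)) {
            if (s %in% seen) match_slot[ii] <- NA_integer_ else seen <- c(seen, s)
          }
        }
      }
    } else {
      match_slot <- rep(NA_integer_, length(mz))
    }
    hit <- !is.na(match_slot)
    if (any(hit)) {
      s <- match_slot[hit]; smz <- mz[hit]; sint <- intensity[hit]
      state$last_mz[s] <- smz; state$last_int[s] <- sint; state$last_rt[s] <- rt
      state$rt_max[s] <- rt
      state$mz_min[s] <- pmin(state$mz_min[s], smz)
      state$mz_max[s] <- pmax(state$mz_max[s], smz)
      state$missed[s] <- 0L
      state$n_pts[s] <- state$n_pts[s] + 1L
      # SmartRoI bookkeeping: running minimum since last fragmentation;
      # the increase/drop/time triggers are evaluated at query time.
      fragged <- s[state$frag_n[s] > 0L]
      if (length(fragged)) {
        fint <- sint[match(fragged, s)]
        state$sr_min_since[fragged] <- pmin(state$sr_min_since[fragged], fint)
      }
      if (p$store_points) {
        for (j in which(hit)) {
          i <- match_slot[j]
          state$pts[[i]]$mz <- c(state$pts[[i]]$mz, mz[j])
          state$pts[[i]]$rt <- c(state$pts[[i]]$rt, rt)
          state$pts[[i]]$int <- c(state$pts[[i]]$int, intensity[j])
        }
      }
      extended <- s
    }
    if (any(!hit)) {
      opened <- vapply(which(!hit), function(j) {
        roi_new_slot(state, mz[j], intensity[j], rt)
      }, integer(1))
    }
  }
  # missed-scan accounting and closure
  not_ext <- setdiff(live_idx, extended)
  closed <- integer()
  if (length(not_ext)) {
    state$missed[not_ext] <- state$missed[not_ext] + 1L
    closed <- not_ext[state$missed[not_ext] > p$max_missed]
    if (length(closed)) state$live[closed] <- FALSE
  }
  invisible(list(extended = extended, opened = opened, closed = closed))
}

#' Snapshot the RoI store as a tibble
#'
#' @param state A [roi_state()].
#' @param live_only Restrict to live RoIs.
#' @return One row per RoI: id, status, bounds, last point, fragmentation
#'   history summary.
#' @export
roi_snapshot <- function(state, live_only = FALSE) {
  stopifnot(inherits(state, "roi_state"))
  idx <- seq_len(state$n)
  if (live_only) idx <- idx[state$live[idx]]
  tibble::tibble(
    roi_id = idx,
    status = ifelse(state$live[idx], "live", "closed"),
    rt_lo = state$rt_min[idx], rt_hi = state$rt_max[idx],
    mz_lo = state$mz_min[idx], mz_hi = state$mz_max[idx],
    last_mz = state$last_mz[idx], last_rt = state$last_rt[idx],
    last_intensity = state$last_int[idx],
    n_points = state$n_pts[idx],
    n_frag = state$frag_n[idx],
    last_frag_rt = state$last_frag_rt[idx],
    frag_max_intensity = state$frag_max_int[idx]
  )
}

#' Record a fragmentation event against RoIs
#'
#' Appends a fragmentation to each RoI's history (vectorised over `idx`):
#' updates the last-fragmentation time, the running maximum precursor
#' intensity, and resets the SmartRoI reference state. Called by the
#' controller bookkeeping after an MS2 scan executes.
#'
#' @param state A [roi_state()].
#' @param idx Integer RoI indices.
#' @param rt Event retention time (seconds).
#' @param intensity Precursor intensity delivered (counts).
#' @return The state, invisibly.
#' @export
roi_record_frag <- function(state, idx, rt, intensity) {
  state$last_frag_rt[idx] <- rt
  state$frag_max_int[idx] <- pmax(state$frag_max_int[idx], intensity)
  state$frag_n[idx] <- state$frag_n[idx] + 1L
  state$sr_frag_int[idx] <- intensity
  state$sr_min_since[idx] <- intensity
  invisible(state)
}

#' Within-injection exclusion weight of RoIs
#'
#' The `[0, 1]` weight a fragmentation strategy multiplies into a RoI's
#' score, replacing the hard exclusion indicator when a SmartRoI or
#' WeightedDEW scheme is selected. Never-fragmented RoIs always weigh 1.
#'
#' @param state A [roi_state()].
#' @param idx Integer RoI indices.
#' @param now Current retention time (seconds).
#' @param cfg A [dew_config()].
#' @return Numeric vector of weights in `[0, 1]`, parallel to `idx`.
#' @export
roi_exclusion_weight <- function(state, idx, now, cfg = dew_config()) {
  stopifnot(inherits(state, "roi_state"), inherits(cfg, "dew_config"))
  lf <- state$last_frag_rt[idx]
  never <- is.na(lf)
  dt <- now - lf
  w <- numeric(length(idx))
  w[never] <- 1
  f <- !never
  if (!any(f)) return(w)
  if (cfg$scheme == "plain") {
    w[f] <- as.numeric(dt[f] > cfg$rt_tol)
  } else if (cfg$scheme == "weighteddew") {
    ramp <- (dt[f] - cfg$t0) / (cfg$rt_tol - cfg$t0)
    w[f] <- pmin(1, pmax(0, ramp))
    w[f][dt[f] >= cfg$rt_tol] <- 1
  } else { # smartroi
    cur <- state$last_int[idx]
    enab <- dt > cfg$reset_length |
      (cur >= state$sr_min_since[idx] * cfg$intensity_increase_factor) |
      (cur < state$sr_frag_int[idx] * cfg$drop_fraction)
    w[f] <- as.numeric(enab[f])
  }
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
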