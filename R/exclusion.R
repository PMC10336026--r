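#' Exclusion-window registry
#'
#' Holds the two kinds of exclusion state a fragmentation strategy keeps:
#' within-injection dynamic exclusion windows (DEWs), which expire with
#' retention time and are cleared at the end of each injection, and
#' carried-over windows (DEW boxes or fragmented-RoI boxes), which persist
#' for the remainder of a multi-injection experiment. Every window is an
#' (rt, m/z) box with the precursor intensity of the fragmentation event
#' that created it.
#'
#' The registry is a mutable store: registering functions modify it in
#' place and return it invisibly.
#'
#' @param rt_pad,mz_pad Symmetric padding (seconds / Daltons) applied to
#'   RoI boxes when they are carried across injections. Defaults to no
#'   padding: a carried RoI box is the RoI's final bounds.
#' @return An `exclusion_registry`.
#' @export
exclusion_registry <- function(rt_pad = 0, mz_pad = 0) {
  e <- new.env(parent = emptyenv())
  e$rt_pad <- rt_pad; e$mz_pad <- mz_pad
  # within-injection DEW boxes
  e$dew <- list(rt_lo = numeric(), rt_hi = numeric(),
                mz_lo = numeric(), mz_hi = numeric(), intensity = numeric())
  # carried-over (between-injection) windows, sorted by mz_lo for queries
  e$car <- list(rt_lo = numeric(), rt_hi = numeric(),
                mz_lo = numeric(), mz_hi = numeric(),
                intensity = numeric(), kind = character(),
                source_injection = integer())
  e$car_max_mz_width <- 0
  # staged for carryover at the next injection rollover
  e$pending_dew <- list(rt_lo = numeric(), rt_hi = numeric(),
                        mz_lo = numeric(), mz_hi = numeric(),
                        intensity = numeric())
  e$pending_roi <- integer()   # RoI slots awaiting finalisation
  class(e) <- "exclusion_registry"
  e
}

# indices of carried windows whose mz interval could contain `mz`
car_mz_slice <- function(reg, mz) {
  n <- length(reg$car$mz_lo)
  if (!n) return(integer())
  # windows with mz_lo in [mz - max_width, mz]; anything else cannot contain mz
  lo <- findInterval(mz - reg$car_max_mz_width, reg$car$mz_lo,
                     left.open = TRUE) + 1L
  hi <- findInterval(mz, reg$car$mz_lo)
  if (hi < lo) return(integer())
  seq.int(lo, hi)
}

#' Is a point inside an active exclusion window?
#'
#' Containment truth for the exclusion indicator: controllers map it to the
#' 0/1 term of the scoring function. Closed intervals on both axes. Expired
#' within-injection DEWs never match.
#'
#' @param registry An [exclusion_registry()].
#' @param mz,rt Query point (Daltons, seconds). Vectorised.
#' @param include Which window sets to consult: `"dew"` (within-injection),
#'   `"carried"`, or both (default). Strategies differ in which sets feed
#'   their indicator.
#' @return Logical vector.
#' @export
is_excluded <- function(registry, mz, rt, include = c("dew", "carried")) {
  stopifnot(inherits(registry, "exclusion_registry"))
  include <- match.arg(include, several.ok = TRUE)
  out <- logical(length(mz))
  if ("dew" %in% include && length(registry$dew$rt_lo)) {
    d <- registry$dew
    for (i in seq_along(mz)) {
      if (out[i]) next
      out[i] <- any(rt[i] >= d$rt_lo & rt[i] <= d$rt_hi &
                    mz[i] >= d$mz_lo & mz[i] <= d$mz_hi)
    }
  }
  if ("carried" %in% include && length(registry$car$rt_lo)) {
    cc <- registry$car
    for (i in seq_along(mz)) {
      if (out[i]) next
      sl <- car_mz_slice(registry, mz[i])
      if (length(sl)) {
        out[i] <- any(mz[i] >= cc$mz_lo[sl] & mz[i] <= cc$mz_hi[sl] &
                      rt[i] >= cc$rt_lo[sl] & rt[i] <= cc$rt_hi[sl])
      }
    }
  }
  out
}

#' Maximum intensity of carried-over windows containing a point
#'
#' The intensity-exclusion lookup: the highest precursor intensity at which
#' the queried location was fragmented in any previous injection. Only
#' carried-over (between-injection) windows are consulted -- within-injection
#' DEWs never contribute. Returns `NA` when no carried window contains the
#' point ("not previously fragmented"); controllers treat the corresponding
#' log term as 0.
#'
#' @inheritParams is_excluded
#' @return Numeric vector; `NA` where no carried window contains the point.
#' @export
phi <- function(registry, mz, rt) {
  stopifnot(inherits(registry, "exclusion_registry"))
  out <- rep(NA_real_, length(mz))
  if (!length(registry$car$rt_lo)) return(out)
  cc <- registry$car
  for (i in seq_along(mz)) {
    sl <- car_mz_slice(registry, mz[i])
    if (length(sl)) {
      hit <- mz[i] >= cc$mz_lo[sl] & mz[i] <= cc$mz_hi[sl] &
        rt[i] >= cc$rt_lo[sl] & rt[i] <= cc$rt_hi[sl]
      if (any(hit)) out[i] <- max(cc$intensity[sl][hit])
    }
  }
  out
}

#' Record a fragmentation event in the registry
#'
#' `mode = "dew_box"` adds a within-injection DEW spanning
#' `[rt, rt + rt_tol]` by `mz +/- mz_tol`; with `carry = TRUE` the same box
#' is also staged to persist across injections (iterative exclusion), its
#' expiry stripped. `mode = "roi_box"` stages a RoI slot so that at the
#' injection rollover its final bounds (optionally padded) become a
#' carried window whose intensity is the maximum precursor intensity over
#' the RoI's fragmentation events.
#'
#' @param registry An [exclusion_registry()].
#' @param mz,rt,intensity The fragmentation event's precursor.
#' @param mode `"dew_box"` or `"roi_box"`.
#' @param rt_tol,mz_tol DEW box extent (seconds forward; Daltons half-width).
#' @param carry Stage a dew_box for between-injection carryover.
#' @param roi_slot RoI index (for `mode = "roi_box"`).
#' @return The registry, invisibly.
#' @export
register_fragmentation <- function(registry, mz, rt, intensity,
                                   mode = c("dew_box", "roi_box"),
                                   rt_tol = 15, mz_tol = 0.01,
                                   carry = FALSE, roi_slot = NULL) {
  stopifnot(inherits(registry, "exclusion_registry"))
  mode <- match.arg(mode)
  if (mode == "dew_box") {
    n <- length(registry$dew$rt_lo) + 1L
    registry$dew$rt_lo[n] <- rt
    registry$dew$rt_hi[n] <- rt + rt_tol
    registry$dew$mz_lo[n] <- mz - mz_tol
    registry$dew$mz_hi[n] <- mz + mz_tol
    registry$dew$intensity[n] <- intensity
    if (carry) {
      m <- length(registry$pending_dew$rt_lo) + 1L
      registry$pending_dew$rt_lo[m] <- rt
      registry$pending_dew$rt_hi[m] <- rt + rt_tol
      registry$pending_dew$mz_lo[m] <- mz - mz_tol
      registry$pending_dew$mz_hi[m] <- mz + mz_tol
      registry$pending_dew$intensity[m] <- intensity
    }
  } else {
    if (is.null(roi_slot)) stop("roi_box mode needs `roi_slot`", call. = FALSE)
    registry$pending_roi <- union(registry$pending_roi, as.integer(roi_slot))
  }
  invisible(registry)
}

# Drop within-injection DEWs that can no longer match (rt_hi < now).
prune_dews <- function(registry, now) {
  keep <- registry$dew$rt_hi >= now
  if (!all(keep)) registry$dew <- lapply(registry$dew, `[`, keep)
  invisible(registry)
}

#' Close an injection: carry staged windows forward
#'
#' Converts the staged carryover state into persistent carried windows:
#' staged DEW boxes are appended as-is (kind `"dew_box"`), staged RoI slots
#' are resolved against the RoI store into their final bounds, padded per
#' the registry's padding, with intensity equal to the maximum precursor
#' intensity over the RoI's fragmentation events (kind `"roi_box"`).
#' Within-injection DEWs are cleared. The carried set only ever grows.
#'
#' @param registry An [exclusion_registry()].
#' @param roi_state The injection's [roi_state()] (or `NULL`).
#' @param injection Index recorded as the windows' source.
#' @return The registry, invisibly.
#' @export
advance_injection <- function(registry, roi_state = NULL, injection = 0L) {
  stopifnot(inherits(registry, "exclusion_registry"))
  add <- list(rt_lo = numeric(), rt_hi = numeric(), mz_lo = numeric(),
              mz_hi = numeric(), intensity = numeric(), kind = character())
  pd <- registry$pending_dew
  if (length(pd$rt_lo)) {
    add$rt_lo <- pd$rt_lo; add$rt_hi <- pd$rt_hi
    add$mz_lo <- pd$mz_lo; add$mz_hi <- pd$mz_hi
    add$intensity <- pd$intensity
    add$kind <- rep("dew_box", length(pd$rt_lo))
  }
  if (length(registry$pending_roi)) {
    if (is.null(roi_state)) stop("pending RoI boxes but no roi_state", call. = FALSE)
    ix <- registry$pending_roi
    add$rt_lo <- c(add$rt_lo, roi_state$rt_min[ix] - registry$rt_pad)
    add$rt_hi <- c(add$rt_hi, roi_state$rt_max[ix] + registry$rt_pad)
    add$mz_lo <- c(add$mz_lo, roi_state$mz_min[ix] - registry$mz_pad)
    add$mz_hi <- c(add$mz_hi, roi_state$mz_max[ix] + registry$mz_pad)
    add$intensity <- c(add$intensity, roi_state$frag_max_int[ix])
    add$kind <- c(add$kind, rep("roi_box", length(ix)))
  }
  if (length(add$rt_lo)) {
    cc <- registry$car
    cc$rt_lo <- c(cc$rt_lo, add$rt_lo); cc$rt_hi <- c(cc$rt_hi, add$rt_hi)
    cc$mz_lo <- c(cc$mz_lo, add$mz_lo); cc$mz_hi <- c(cc$mz_hi, add$mz_hi)
    cc$intensity <- c(cc$intensity, add$intensity)
    cc$kind <- c(cc$kind, add$kind)
    cc$source_injection <- c(cc$source_injection,
                             rep(as.integer(injection), length(add$rt_lo)))
    o <- order(cc$mz_lo)
    registry$car <- lapply(cc, `[`, o)
    registry$car_max_mz_width <- max(registry$car$mz_hi - registry$car$mz_lo)
  }
  registry$dew <- lapply(registry$dew, function(x) x[0])
  registry$pending_dew <- lapply(registry$pending_dew, function(x) x[0])
  registry$pending_roi <- integer()
  invisible(registry)
}

#' Windows currently held by a registry
#'
#' @param registry An [exclusion_registry()].
#' @return A tibble, one row per window: `kind` (`"dew"` for active
#'   within-injection windows, else the carried kind), bounds, `intensity`,
#'   `source_injection` (`NA` for within-injection windows).
#' @export
registry_windows <- function(registry) {
  stopifnot(inherits(registry, "exclusion_registry"))
  d <- registry$dew; cc <- registry$car
  tibble::tibble(
    kind = c(rep("dew", length(d$rt_lo)), cc$kind),
    rt_lo = c(d$rt_lo, cc$rt_lo), rt_hi = c(d$rt_hi, cc$rt_hi),
    mz_lo = c(d$mz_lo, cc$mz_lo), mz_hi = c(d$mz_hi, cc$mz_hi),
    intensity = c(d$intensity, cc$intensity),
    source_injection = c(rep(NA_integer_, length(d$rt_lo)),
                         cc$source_injection)
  )
}

#' Serialise / restore an exclusion registry
#'
#' One CSV row per window (kind, bounds, intensity, source injection) so
#' multi-injection experiments can be resumed. Only carried-over windows
#' are written: within-injection DEWs do not survive an injection anyway.
#'
#' @param registry An [exclusion_registry()].
#' @param path CSV file path.
#' @return `write_registry()`: `path`, invisibly. `read_registry()`: a
#'   restored [exclusion_registry()].
#' @export
write_registry <- function(registry, path) {
  df <- registry_windows(registry)
  df <- df[df$kind != "dew", , drop = FALSE]
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_registry
#' @param rt_pad,mz_pad Padding for the restored registry (see
#'   [exclusion_registry()]).
#' @export
read_registry <- function(path, rt_pad = 0, mz_pad = 0) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  reg <- exclusion_registry(rt_pad = rt_pad, mz_pad = mz_pad)
  if (nrow(df)) {
    o <- order(df$mz_lo)
    reg$car <- list(rt_lo = df$rt_lo[o], rt_hi = df$rt_hi[o],
                    mz_lo = df$mz_lo[o], mz_hi = df$mz_hi[o],
                    intensity = df$intensity[o],
                    kind = as.character(df$kind[o]),
                    source_injection = as.integer(df$source_injection[o]))
    reg$car_max_mz_width <- max(reg$car$mz_hi - reg$car$mz_lo)
  }
  reg
}

# Carried windows overlapping a rect, as parallel vectors (used by the
# non-overlap scores). Returns integer indices into registry$car.
car_overlapping_rect <- function(registry, rt_lo, rt_hi, mz_lo, mz_hi) {
  cc <- registry$car
  n <- length(cc$mz_lo)
  if (!n) return(integer())
  lo <- findInterval(mz_lo - registry$car_max_mz_width, cc$mz_lo,
                     left.open = TRUE) + 1L
  hi <- findInterval(mz_hi, cc$mz_lo)
  if (hi < lo) return(integer())
  sl <- seq.int(lo, hi)
  sl[cc$mz_hi[sl] >= mz_lo & cc$rt_lo[sl] <= rt_hi & cc$rt_hi[sl] >= rt_lo]
}
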