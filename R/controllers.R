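STRATEGIES <- c("topn", "topn_exclusion", "topn_roi", "topn_exclusion_roi",
                "hard_roi_exclusion", "intensity_roi_exclusion",
                "non_overlap", "intensity_non_overlap")

#' Fragmentation-strategy configuration
#'
#' One configuration object drives all eight strategies, which share a
#' single scoring function: an exclusion term, a minimum-intensity gate,
#' and a strategy-specific core built from the candidate's log intensity.
#'
#' Strategy feature matrix (what each carries between injections and how
#' within-injection exclusion works):
#' * `topn` -- precursor DEW boxes, nothing carried.
#' * `topn_exclusion` -- DEW boxes, carried forward across injections
#'   (iterative exclusion).
#' * `topn_roi` -- RoI-tied within-injection exclusion, nothing carried.
#' * `topn_exclusion_roi` -- RoI-tied exclusion plus carried DEW boxes
#'   (the boxes a non-RoI method would have left behind).
#' * `hard_roi_exclusion` -- carried boxes are fragmented RoIs; a candidate
#'   whose precursor falls inside one is excluded outright.
#' * `intensity_roi_exclusion` -- carried RoI boxes reduce the candidate's
#'   log intensity by the highest previously fragmented intensity there.
#' * `non_overlap` -- the candidate RoI's log intensity is weighted by the
#'   fraction of its area not covered by carried RoI boxes.
#' * `intensity_non_overlap` -- area and intensity combined: each distinct
#'   overlap region contributes its intensity difference raised to its
#'   proportional area; the score is the log of the summed contributions.
#'
#' @param strategy One of the eight strategy names above.
#' @param n Maximum MS2 scans per duty cycle (`N`).
#' @param min_intensity Minimum precursor intensity (counts) for
#'   scheduling.
#' @param dew A [dew_config()]; the scheme replaces the hard exclusion
#'   indicator for RoI-based strategies (non-RoI strategies always use
#'   plain DEW boxes).
#' @param isolation_width Precursor isolation width (Daltons).
#' @param dew_rt_tol,dew_mz_tol DEW box extent for non-RoI strategies:
#'   seconds forward in rt, Daltons half-width in m/z.
#' @param roi [roi_params()] for RoI-based strategies.
#' @param rt_pad,mz_pad Padding applied to carried RoI boxes.
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(strategy = "topn", n = 10, min_intensity = 5000,
                              dew = dew_config(), isolation_width = 0.7,
                              dew_rt_tol = dew$rt_tol, dew_mz_tol = 0.01,
                              roi = roi_params(), rt_pad = 0, mz_pad = 0) {
  if (!strategy %in% STRATEGIES) {
    stop("unknown strategy: ", strategy, call. = FALSE)
  }
  stopifnot(n >= 1, min_intensity >= 0, isolation_width > 0)
  structure(list(strategy = strategy, n = as.integer(n),
                 min_intensity = min_intensity, dew = dew,
                 isolation_width = isolation_width,
                 dew_rt_tol = dew_rt_tol, dew_mz_tol = dew_mz_tol,
                 roi = roi, rt_pad = rt_pad, mz_pad = mz_pad),
            class = "controller_config")
}

strategy_uses_roi <- function(strategy) {
  !strategy %in% c("topn", "topn_exclusion")
}

strategy_carryover <- function(strategy) {
  switch(strategy,
         topn = , topn_roi = "none",
         topn_exclusion = , topn_exclusion_roi = "dew",
         "roi")
}

# does the carried set feed the hard exclusion indicator?
strategy_iex_carried <- function(strategy) {
  strategy %in% c("topn_exclusion", "topn_exclusion_roi", "hard_roi_exclusion")
}

#' Score duty-cycle candidates under a strategy
#'
#' The parametric scoring function shared by every strategy: an exclusion
#' weight (hard 0/1, or the SmartRoI/WeightedDEW weight for RoI-based
#' strategies), an intensity gate at the configured minimum, and a
#' strategy core on the natural-log intensity. Scores are non-negative;
#' only candidates scoring above zero are ever scheduled.
#'
#' @param candidates A tibble with columns `mz`, `rt`, `intensity`, and for
#'   RoI-based strategies `roi` (RoI slot index) plus the RoI bounds
#'   `rt_lo`, `rt_hi`, `mz_lo`, `mz_hi` at query time.
#' @param registry An [exclusion_registry()].
#' @param cfg A [controller_config()].
#' @param now Current retention time (seconds).
#' @param roi_state The live [roi_state()] (RoI-based strategies).
#' @return Numeric score vector, parallel to `candidates`.
#' @export
score_candidates <- function(candidates, registry, cfg, now, roi_state = NULL) {
  stopifnot(inherits(cfg, "controller_config"))
  n <- nrow(candidates)
  if (!n) return(numeric())
  strat <- cfg$strategy
  lam <- candidates$intensity
  gate <- lam >= cfg$min_intensity
  out <- numeric(n)
  act <- which(gate)
  if (!length(act)) return(out)

  # exclusion weight -------------------------------------------------------
  if (!strategy_uses_roi(strat)) {
    inc <- if (strategy_iex_carried(strat)) c("dew", "carried") else "dew"
    w <- 1 - as.numeric(is_excluded(registry, candidates$mz[act],
                                    candidates$rt[act], include = inc))
  } else {
    w <- roi_exclusion_weight(roi_state, candidates$roi[act], now, cfg$dew)
    if (strategy_iex_carried(strat)) {
      w <- w * (1 - as.numeric(is_excluded(registry, candidates$mz[act],
                                           candidates$rt[act],
                                           include = "carried")))
    }
  }
  act <- act[w > 0]
  w <- w[w > 0]
  if (!length(act)) return(out)

  # strategy core on ln(lambda) -------------------------------------------
  core <- switch(
    strat,
    topn = , topn_exclusion = , topn_roi = , topn_exclusion_roi = ,
    hard_roi_exclusion = log(lam[act]),
    intensity_roi_exclusion = {
      ph <- phi(registry, candidates$mz[act], candidates$rt[act])
      logphi <- ifelse(is.na(ph) | ph <= 0, 0, log(ph))
      pmax(0, log(lam[act]) - logphi)
    },
    non_overlap = {
      vapply(seq_along(act), function(k) {
        i <- act[k]
        bx <- car_overlapping_rect(registry, candidates$rt_lo[i],
                                   candidates$rt_hi[i], candidates$mz_lo[i],
                                   candidates$mz_hi[i])
        if (!length(bx)) return(log(lam[i]))
        cc <- registry$car
        prop <- non_overlap_prop_core(
          candidates$rt_lo[i], candidates$rt_hi[i],
          candidates$mz_lo[i], candidates$mz_hi[i],
          cc$rt_lo[bx], cc$rt_hi[bx], cc$mz_lo[bx], cc$mz_hi[bx])
        prop * log(lam[i])
      }, numeric(1))
    },
    intensity_non_overlap = {
      vapply(seq_along(act), function(k) {
        i <- act[k]
        bx <- car_overlapping_rect(registry, candidates$rt_lo[i],
                                   candidates$rt_hi[i], candidates$mz_lo[i],
                                   candidates$mz_hi[i])
        if (!length(bx)) return(log(lam[i]))
        cc <- registry$car
        # a box covering the whole candidate at >= its intensity zeroes
        # every region term; skip the dissection
        covers <- cc$rt_lo[bx] <= candidates$rt_lo[i] &
          cc$rt_hi[bx] >= candidates$rt_hi[i] &
          cc$mz_lo[bx] <= candidates$mz_lo[i] &
          cc$mz_hi[bx] >= candidates$mz_hi[i]
        if (any(covers & cc$intensity[bx] >= lam[i])) return(0)
        s <- intensity_region_sum_core(
          candidates$rt_lo[i], candidates$rt_hi[i],
          candidates$mz_lo[i], candidates$mz_hi[i], lam[i],
          cc$rt_lo[bx], cc$rt_hi[bx], cc$mz_lo[bx], cc$mz_hi[bx],
          cc$intensity[bx])
        if (s <= 1) 0 else log(s)
      }, numeric(1))
    },
    stop("unknown strategy: ", strat, call. = FALSE)
  )
  out[act] <- w * core
  pmax(out, 0)
}

#' Rank candidates and emit up to N scan requests
#'
#' Candidates are scored with [score_candidates()] and ranked by
#' descending score, then descending raw intensity, then ascending m/z;
#' the top `min(N, number scoring above zero)` become MS2 scan requests.
#' A duty cycle may therefore end with fewer than `N` MS2 scans.
#'
#' @inheritParams score_candidates
#' @return A tibble of scan requests: `precursor_mz`,
#'   `precursor_intensity`, `isolation_width`, `score`, `roi`.
#' @export
schedule_duty_cycle <- function(candidates, registry, cfg, now,
                                roi_state = NULL) {
  sc <- score_candidates(candidates, registry, cfg, now, roi_state)
  keep <- which(sc > 0)
  empty <- tibble::tibble(precursor_mz = numeric(),
                          precursor_intensity = numeric(),
                          isolation_width = numeric(), score = numeric(),
                          roi = integer())
  if (!length(keep)) return(empty)
  o <- keep[order(-sc[keep], -candidates$intensity[keep],
                  candidates$mz[keep])]
  o <- o[seq_len(min(cfg$n, length(o)))]
  tibble::tibble(
    precursor_mz = candidates$mz[o],
    precursor_intensity = candidates$intensity[o],
    isolation_width = cfg$isolation_width,
    score = sc[o],
    roi = if (!is.null(candidates$roi)) candidates$roi[o]
          else rep(NA_integer_, length(o))
  )
}

#' Commit an executed MS2 scan to the exclusion state
#'
#' Appends the fragmentation event to the target RoI (RoI strategies) and
#' registers the exclusion state the strategy keeps: a within-injection DEW
#' box for non-RoI strategies (staged for carryover under iterative
#' exclusion), a carried DEW-box record for `topn_exclusion_roi`, or the
#' fragmented RoI staged to become a carried box at injection end for the
#' multi-sample RoI strategies.
#'
#' @param registry An [exclusion_registry()].
#' @param cfg A [controller_config()].
#' @param mz,rt,intensity The executed precursor (m/z, execution rt,
#'   intensity at execution).
#' @param roi RoI slot index or `NA`.
#' @param roi_state The [roi_state()] (RoI strategies).
#' @return The registry, invisibly.
#' @export
on_ms2_performed <- function(registry, cfg, mz, rt, intensity, roi = NA,
                             roi_state = NULL) {
  strat <- cfg$strategy
  if (strategy_uses_roi(strat) && !is.na(roi)) {
    roi_record_frag(roi_state, roi, rt, intensity)
  }
  carry <- strategy_carryover(strat)
  if (!strategy_uses_roi(strat)) {
    register_fragmentation(registry, mz, rt, intensity, mode = "dew_box",
                           rt_tol = cfg$dew_rt_tol, mz_tol = cfg$dew_mz_tol,
                           carry = carry == "dew")
  } else if (carry == "dew") {
    # record the DEW-box geometry a non-RoI method would have produced,
    # for carryover only (within-injection exclusion is RoI-tied)
    m <- length(registry$pending_dew$rt_lo) + 1L
    registry$pending_dew$rt_lo[m] <- rt
    registry$pending_dew$rt_hi[m] <- rt + cfg$dew_rt_tol
    registry$pending_dew$mz_lo[m] <- mz - cfg$dew_mz_tol
    registry$pending_dew$mz_hi[m] <- mz + cfg$dew_mz_tol
    registry$pending_dew$intensity[m] <- intensity
  } else if (carry == "roi" && !is.na(roi)) {
    register_fragmentation(registry, mz, rt, intensity, mode = "roi_box",
                           roi_slot = roi)
  }
  invisible(registry)
}
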