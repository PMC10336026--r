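#' Injection schedule for a multi-injection experiment
#'
#' The sample injected at each position, the per-injection acquisition
#' length, and the fixed MS1/MS2 scan durations. The default durations
#' (0.59 s survey, 0.19 s fragmentation) are typical averaged scan times
#' for a tribrid Orbitrap and make simulated runs exactly reproducible.
#'
#' @param samples Character vector of sample ids in injection order (a
#'   sample may repeat).
#' @param max_rt Acquisition length per injection (seconds).
#' @param ms1_duration,ms2_duration Scan durations (seconds).
#' @return A list of class `injection_schedule`.
#' @export
injection_schedule <- function(samples, max_rt = 440,
                               ms1_duration = 0.59, ms2_duration = 0.19) {
  stopifnot(length(samples) >= 1, max_rt > 0,
            ms1_duration > 0, ms2_duration > 0)
  structure(list(samples = as.character(samples), max_rt = max_rt,
                 ms1_duration = ms1_duration, ms2_duration = ms2_duration),
            class = "injection_schedule")
}

#' Interleaved sample order for a samples-times-repeats design
#'
#' Round-robin ordering (1-2-...-k-1-2-...) so that at any point no sample
#' has been injected more than once more than any other; shared chemicals
#' are collected first and sample-specific ones remain reachable later.
#'
#' @param samples Unique sample ids.
#' @param repeats Number of injections per sample.
#' @return Character vector of length `length(samples) * repeats`.
#' @export
interleave_samples <- function(samples, repeats) {
  rep(samples, times = repeats)
}

# chemical table for one sample: chemicals joined to the sample's factors,
# sorted by m/z (scan points must come out sorted)
sample_chemicals <- function(cohort, sample) {
  map <- cohort$sample_map[cohort$sample_map$sample == sample, ]
  if (!nrow(map)) stop("unknown sample id: ", sample, call. = FALSE)
  df <- dplyr::inner_join(cohort$chemicals, map[, c("chem_id", "factor")],
                          by = "chem_id")
  df[order(df$mz), ]
}

#' Run one injection on the virtual instrument
#'
#' Alternates duty cycles until the clock passes `max_rt`: one MS1 scan
#' whose points are each chemical's chromatogram evaluated at the scan's
#' retention time (values at or below the detection floor omitted), then
#' the controller's scheduled MS2 scans, each advancing the clock by its
#' fixed duration. MS2 precursor intensity is the most intense
#' chromatogram value inside the isolation window at the MS2 scan's own
#' clock time, so intensity-based exclusion sees what the instrument
#' would. Every fragmentation event is logged.
#'
#' @param chems Chemicals tibble for the injected sample (with a `factor`
#'   column), sorted by m/z.
#' @param cfg A [controller_config()].
#' @param registry The experiment's [exclusion_registry()] (carried state
#'   from earlier injections; modified in place).
#' @param schedule An [injection_schedule()] (only durations and `max_rt`
#'   are used here).
#' @param injection,sample Labels recorded in the event log.
#' @param detection_floor Minimum simulated MS1 intensity (counts).
#' @param mz_noise_ppm Instrument mass-accuracy scatter (s.d., ppm) applied
#'   to every MS1 point; 0 disables it. Peak heights and retention times
#'   are untouched, so acquisition decisions driven by intensity are
#'   unaffected, but RoIs acquire a realistic (non-degenerate) m/z extent.
#' @param return_scans Keep full scan records (needed for mzML output).
#' @return A list: `events` (tibble: `injection`, `sample`, `cycle` -- the
#'   duty-cycle index --, `rt`, `precursor_mz`, `precursor_intensity` --
#'   delivered at execution --, `ms1_intensity` -- the survey-scan
#'   intensity the scheduling decision saw --, `score`, `roi`), `n_ms1`,
#'   `n_ms2`, `roi_state`, and `scans` (tibble or `NULL`).
#' @export
run_injection <- function(chems, cfg, registry, schedule,
                          injection = 1L, sample = "S01",
                          detection_floor = 0, mz_noise_ppm = 2,
                          return_scans = FALSE) {
  stopifnot(inherits(cfg, "controller_config"),
            inherits(registry, "exclusion_registry"),
            inherits(schedule, "injection_schedule"))
  uses_roi <- strategy_uses_roi(cfg$strategy)
  rstate <- if (uses_roi) roi_state(cfg$roi) else NULL
  clock <- 0
  n_ms1 <- 0L; n_ms2 <- 0L
  ev <- list(rt = numeric(), mz = numeric(), int = numeric(),
             ms1_int = numeric(), score = numeric(), roi = integer(),
             cycle = integer())
  scans <- if (return_scans) list() else NULL
  half_iso <- cfg$isolation_width / 2
  has_chem <- nrow(chems) > 0

  while (clock <= schedule$max_rt) {
    rt1 <- clock
    clock <- clock + schedule$ms1_duration
    n_ms1 <- n_ms1 + 1L
    if (has_chem) {
      intens <- chromatogram_at(chems, rt1, chems$factor)
      vis <- intens > detection_floor
      p_mz <- chems$mz[vis]; p_int <- intens[vis]
      if (mz_noise_ppm > 0 && length(p_mz)) {
        # instrument mass error: ppm-scale scatter around the true m/z;
        # this is what gives RoIs their m/z extent
        p_mz <- p_mz * (1 + stats::rnorm(length(p_mz), 0, mz_noise_ppm * 1e-6))
        o <- order(p_mz)
        p_mz <- p_mz[o]; p_int <- p_int[o]
      }
    } else {
      p_mz <- numeric(); p_int <- numeric()
    }
    if (return_scans) {
      scans[[length(scans) + 1L]] <- list(
        ms_level = 1L, rt = rt1, peaks = cbind(mz = p_mz, intensity = p_int),
        precursor_mz = NA_real_, precursor_intensity = NA_real_,
        isolation_width = NA_real_)
    }
    prune_dews(registry, rt1)

    # candidates
    if (uses_roi) {
      upd <- roi_update(rstate, p_mz, p_int, rt1)
      slots <- c(upd$extended, upd$opened)
      slots <- slots[rstate$last_int[slots] >= cfg$min_intensity]
      cand <- tibble::tibble(
        mz = rstate$last_mz[slots], rt = rt1,
        intensity = rstate$last_int[slots], roi = slots,
        rt_lo = rstate$rt_min[slots], rt_hi = rstate$rt_max[slots],
        mz_lo = rstate$mz_min[slots], mz_hi = rstate$mz_max[slots])
    } else {
      keep <- p_int >= cfg$min_intensity
      cand <- tibble::tibble(mz = p_mz[keep], rt = rt1,
                             intensity = p_int[keep], roi = NA_integer_)
    }
    reqs <- schedule_duty_cycle(cand, registry, cfg, rt1, rstate)
    if (nrow(reqs)) {
      for (j in seq_len(nrow(reqs))) {
        rt2 <- clock
        clock <- clock + schedule$ms2_duration
        n_ms2 <- n_ms2 + 1L
        # intensity delivered at execution time
        exec_int <- 0
        if (has_chem) {
          in_win <- abs(chems$mz - reqs$precursor_mz[j]) <= half_iso
          if (any(in_win)) {
            exec_int <- max(chromatogram_at(chems[in_win, ], rt2,
                                            chems$factor[in_win]))
          }
        }
        k <- length(ev$rt) + 1L
        ev$rt[k] <- rt2; ev$mz[k] <- reqs$precursor_mz[j]
        ev$int[k] <- exec_int
        ev$ms1_int[k] <- reqs$precursor_intensity[j]
        ev$score[k] <- reqs$score[j]
        ev$roi[k] <- reqs$roi[j]; ev$cycle[k] <- n_ms1
        on_ms2_performed(registry, cfg, reqs$precursor_mz[j], rt2, exec_int,
                         roi = reqs$roi[j], roi_state = rstate)
        if (return_scans) {
          frag_mz <- reqs$precursor_mz[j] * c(0.3, 0.5, 0.8)
          scans[[length(scans) + 1L]] <- list(
            ms_level = 2L, rt = rt2,
            peaks = cbind(mz = frag_mz,
                          intensity = exec_int * c(0.2, 0.5, 0.3)),
            precursor_mz = reqs$precursor_mz[j],
            precursor_intensity = exec_int,
            isolation_width = reqs$isolation_width[j])
        }
      }
    }
  }
  events <- tibble::tibble(
    injection = as.integer(injection), sample = sample, cycle = ev$cycle,
    rt = ev$rt, precursor_mz = ev$mz, precursor_intensity = ev$int,
    ms1_intensity = ev$ms1_int, score = ev$score, roi = ev$roi)
  scans_tbl <- NULL
  if (return_scans) {
    scans_tbl <- tibble::tibble(
      ms_level = vapply(scans, `[[`, integer(1), "ms_level"),
      rt = vapply(scans, `[[`, numeric(1), "rt"),
      precursor_mz = vapply(scans, `[[`, numeric(1), "precursor_mz"),
      precursor_intensity = vapply(scans, `[[`, numeric(1),
                                   "precursor_intensity"),
      isolation_width = vapply(scans, `[[`, numeric(1), "isolation_width"),
      peaks = lapply(scans, `[[`, "peaks"))
  }
  list(events = events, n_ms1 = n_ms1, n_ms2 = n_ms2,
       roi_state = rstate, scans = scans_tbl)
}

#' Run a multi-injection, multi-sample experiment
#'
#' Executes the schedule's injections in order on the virtual instrument,
#' threading carried-over exclusion state through the registry according
#' to the strategy, and returns the pooled fragmentation-event log. A
#' fixed seed reproduces the experiment exactly.
#'
#' @param cohort A [generate_cohort()] result (or a compatible list with
#'   `chemicals` and `sample_map`).
#' @param cfg A [controller_config()].
#' @param schedule An [injection_schedule()]; its `samples` must exist in
#'   the cohort.
#' @param seed Integer seed (only consumed by optional rt jitter, but set
#'   regardless so runs are reproducible bit-for-bit).
#' @param rt_jitter Per-injection, per-chemical apex jitter (s.d.,
#'   seconds); 0 disables it, matching the package's deterministic
#'   baseline conditions (retention time is reproducible across
#'   injections; only the mass axis carries measurement noise).
#' @param detection_floor Minimum simulated MS1 intensity (counts).
#' @param mz_noise_ppm Instrument mass-accuracy scatter (s.d., ppm); see
#'   [run_injection()].
#' @param return_scans Keep full scan records for every injection.
#' @param out_dir If non-`NULL`, write one mzML per injection here.
#' @return A list of class `dda_experiment`: `events` (pooled tibble),
#'   `injections` (tibble: `injection`, `sample`, `n_ms1`, `n_ms2`),
#'   `registry`, `scans` (list or `NULL`), `cfg`, `schedule`.
#' @export
run_experiment <- function(cohort, cfg, schedule, seed = 1,
                           rt_jitter = 0, detection_floor = 0,
                           mz_noise_ppm = 2,
                           return_scans = FALSE, out_dir = NULL) {
  stopifnot(inherits(cfg, "controller_config"),
            inherits(schedule, "injection_schedule"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  registry <- exclusion_registry(rt_pad = cfg$rt_pad, mz_pad = cfg$mz_pad)
  all_events <- vector("list", length(schedule$samples))
  inj_rows <- vector("list", length(schedule$samples))
  scans_out <- if (return_scans) vector("list", length(schedule$samples)) else NULL
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  for (i in seq_along(schedule$samples)) {
    s <- schedule$samples[i]
    chems <- sample_chemicals(cohort, s)
    if (rt_jitter > 0) {
      chems$apex_rt <- chems$apex_rt + stats::rnorm(nrow(chems), 0, rt_jitter)
    }
    res <- run_injection(chems, cfg, registry, schedule,
                         injection = i, sample = s,
                         detection_floor = detection_floor,
                         mz_noise_ppm = mz_noise_ppm,
                         return_scans = return_scans || !is.null(out_dir))
    all_events[[i]] <- res$events
    inj_rows[[i]] <- tibble::tibble(injection = i, sample = s,
                                    n_ms1 = res$n_ms1, n_ms2 = res$n_ms2)
    if (!is.null(res$scans) && return_scans) scans_out[[i]] <- res$scans
    if (!is.null(out_dir) && !is.null(res$scans)) {
      write_mzml(res$scans,
                 file.path(out_dir, sprintf("injection_%02d_%s.mzML", i, s)))
    }
    advance_injection(registry, res$roi_state, injection = i)
  }
  structure(list(events = dplyr::bind_rows(all_events),
                 injections = dplyr::bind_rows(inj_rows),
                 registry = registry,
                 scans = scans_out,
                 cfg = cfg, schedule = schedule),
            class = "dda_experiment")
}

#' @export
print.dda_experiment <- function(x, ...) {
  cat("<dda_experiment> strategy ", x$cfg$strategy, ": ",
      nrow(x$injections), " injection(s), ",
      nrow(x$events), " MS2 events\n", sep = "")
  invisible(x)
}
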