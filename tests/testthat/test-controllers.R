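# single candidate helper for non-RoI strategies
cand1 <- function(mz, rt, intensity) {
  tibble::tibble(mz = mz, rt = rt, intensity = intensity, roi = NA_integer_)
}

# build a one-RoI state with given bounds/intensity; returns list(state, cand)
roi_cand <- function(rt_lo, rt_hi, mz_lo, mz_hi, intensity,
                     fragged_at = NULL) {
  st <- roi_state(roi_params(min_intensity = 0, mz_tol_unit = "da",
                             mz_tol = abs(mz_hi - mz_lo) + 1))
  roi_update(st, mz_lo, intensity, rt_lo)
  if (rt_hi > rt_lo) roi_update(st, mz_hi, intensity, rt_hi)
  if (!is.null(fragged_at)) roi_record_frag(st, 1L, fragged_at, intensity)
  cand <- tibble::tibble(mz = st$last_mz[1], rt = st$last_rt[1],
                         intensity = st$last_int[1], roi = 1L,
                         rt_lo = st$rt_min[1], rt_hi = st$rt_max[1],
                         mz_lo = st$mz_min[1], mz_hi = st$mz_max[1])
  list(state = st, cand = cand)
}

carried_box <- function(reg, rt_lo, rt_hi, mz_lo, mz_hi, intensity) {
  st <- roi_state(roi_params(min_intensity = 0, mz_tol_unit = "da",
                             mz_tol = abs(mz_hi - mz_lo) + 1))
  roi_update(st, mz_lo, intensity, rt_lo)
  if (rt_hi > rt_lo) roi_update(st, mz_hi, intensity, rt_hi)
  roi_record_frag(st, 1L, rt_lo, intensity)
  register_fragmentation(reg, mz_lo, rt_lo, intensity, mode = "roi_box",
                         roi_slot = 1L)
  advance_injection(reg, st, injection = 1L)
  reg
}

test_that("topn scores by natural-log intensity above the gate", {
  reg <- exclusion_registry()
  cfg <- controller_config("topn", min_intensity = 5000)
  expect_equal(score_candidates(cand1(300, 10, 1e6), reg, cfg, 10),
               log(1e6))
  # below the minimum-intensity gate
  expect_equal(score_candidates(cand1(300, 10, 4999), reg, cfg, 10), 0)
  # inside a DEW
  register_fragmentation(reg, 300, 5, 1e6, mode = "dew_box", rt_tol = 15,
                         mz_tol = 0.01)
  expect_equal(score_candidates(cand1(300, 10, 1e6), reg, cfg, 10), 0)
})

test_that("intensity exclusion subtracts the previously seen log intensity", {
  reg <- carried_box(exclusion_registry(), 0, 20, 299.99, 300.01, 1e4)
  cfg <- controller_config("intensity_roi_exclusion", min_intensity = 5000)
  rc <- roi_cand(5, 15, 300, 300, 1e6)
  expect_equal(score_candidates(rc$cand, reg, cfg, 15, rc$state),
               log(1e6) - log(1e4))
  # refragmenting at lower intensity than before is pointless: clamped to 0
  rc2 <- roi_cand(5, 15, 300, 300, 9e3)
  expect_equal(score_candidates(rc2$cand, reg, cfg, 15, rc2$state), 0)
})

test_that("non-overlap weights log intensity by the uncovered fraction", {
  reg <- carried_box(exclusion_registry(), 1, 3, 1, 3, 100)
  cfg <- controller_config("non_overlap", min_intensity = 0)
  rc <- roi_cand(0, 2, 0, 2, 1000)
  expect_equal(score_candidates(rc$cand, reg, cfg, 2, rc$state),
               0.75 * log(1000))
})

test_that("intensity non-overlap matches independent region enumeration", {
  reg <- carried_box(exclusion_registry(), 1, 3, 1, 3, 100)
  cfg <- controller_config("intensity_non_overlap", min_intensity = 0)
  rc <- roi_cand(0, 2, 0, 2, 1000)
  expect_equal(score_candidates(rc$cand, reg, cfg, 2, rc$state),
               log(1000^0.75 + 900^0.25), tolerance = 1e-9)
})

test_that("with empty exclusion state the RoI strategies reduce to ln(lambda)", {
  for (strat in c("topn_roi", "non_overlap", "intensity_non_overlap",
                  "intensity_roi_exclusion", "hard_roi_exclusion")) {
    reg <- exclusion_registry()
    cfg <- controller_config(strat, min_intensity = 5000)
    rc <- roi_cand(0, 2, 400, 400, 2e5)
    expect_equal(score_candidates(rc$cand, reg, cfg, 2, rc$state),
                 log(2e5), info = strat)
  }
})

test_that("scores are monotone in candidate intensity", {
  reg <- carried_box(exclusion_registry(), 1, 3, 1, 3, 5e4)
  lams <- c(6e3, 1e4, 1e5, 1e6, 1e7)
  for (strat in c("topn", "topn_exclusion", "intensity_roi_exclusion",
                  "non_overlap", "intensity_non_overlap")) {
    cfg <- controller_config(strat, min_intensity = 5000)
    sc <- vapply(lams, function(l) {
      if (strat %in% c("topn", "topn_exclusion")) {
        score_candidates(cand1(700, 2, l), reg, cfg, 2)
      } else {
        rc <- roi_cand(0, 2, 0, 2, l)
        score_candidates(rc$cand, reg, cfg, 2, rc$state)
      }
    }, numeric(1))
    expect_true(all(diff(sc) >= 0), info = strat)
  }
})

test_that("full cover by an equal-or-brighter carried box forbids fragmentation", {
  for (strat in c("hard_roi_exclusion", "intensity_roi_exclusion",
                  "intensity_non_overlap")) {
    reg <- carried_box(exclusion_registry(), -1, 3, 199, 201, 1e6)
    cfg <- controller_config(strat, min_intensity = 5000)
    rc <- roi_cand(0, 2, 200, 200, 1e6)
    expect_equal(score_candidates(rc$cand, reg, cfg, 2, rc$state), 0,
                 info = strat)
  }
})

test_that("duty-cycle scheduling takes the top N positive scores", {
  reg <- exclusion_registry()
  cfg <- controller_config("topn", n = 3, min_intensity = 5000)
  cand <- tibble::tibble(mz = c(100, 200, 300, 400, 500), rt = 10,
                         intensity = c(1e6, 5e5, 2e6, 8e5, 6e5),
                         roi = NA_integer_)
  reqs <- schedule_duty_cycle(cand, reg, cfg, 10)
  expect_equal(nrow(reqs), 3L)
  expect_equal(reqs$precursor_mz, c(300, 100, 400))
  expect_true(all(reqs$precursor_intensity >= cfg$min_intensity))
  expect_true(all(reqs$score > 0))
})

test_that("identical scores schedule the lower m/z first", {
  reg <- exclusion_registry()
  cfg <- controller_config("topn", n = 2, min_intensity = 0)
  cand <- tibble::tibble(mz = c(500, 200), rt = 1, intensity = c(1e5, 1e5),
                         roi = NA_integer_)
  reqs <- schedule_duty_cycle(cand, reg, cfg, 1)
  expect_equal(reqs$precursor_mz, c(200, 500))
})

test_that("a cycle with every candidate excluded emits no requests", {
  reg <- exclusion_registry()
  register_fragmentation(reg, 100, 0, 1e6, mode = "dew_box", rt_tol = 50,
                         mz_tol = 0.05)
  cfg <- controller_config("topn", n = 5, min_intensity = 5000)
  reqs <- schedule_duty_cycle(cand1(100, 10, 1e6), reg, cfg, 10)
  expect_equal(nrow(reqs), 0L)
})

test_that("unknown strategies are rejected", {
  expect_error(controller_config("bogus"), "unknown strategy")
})

test_that("ms2 bookkeeping registers the state each strategy carries", {
  # topn: within-injection DEW only, nothing carried
  reg <- exclusion_registry()
  cfg <- controller_config("topn")
  on_ms2_performed(reg, cfg, 150, 100, 1e5)
  advance_injection(reg, injection = 1L)
  expect_equal(nrow(registry_windows(reg)), 0L)

  # topn_exclusion: the same DEW box is carried forward
  reg <- exclusion_registry()
  cfg <- controller_config("topn_exclusion")
  on_ms2_performed(reg, cfg, 150, 100, 1e5)
  advance_injection(reg, injection = 1L)
  w <- registry_windows(reg)
  expect_equal(w$kind, "dew_box")
  expect_equal(w$intensity, 1e5)

  # hard_roi_exclusion: the fragmented RoI becomes a carried box
  reg <- exclusion_registry()
  cfg <- controller_config("hard_roi_exclusion")
  st <- roi_state(roi_params(min_intensity = 0))
  roi_update(st, 150, 1e5, 95)
  on_ms2_performed(reg, cfg, 150, 96, 1e5, roi = 1L, roi_state = st)
  advance_injection(reg, st, injection = 1L)
  w <- registry_windows(reg)
  expect_equal(w$kind, "roi_box")
  expect_equal(w$intensity, 1e5)
})
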