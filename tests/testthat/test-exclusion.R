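test_that("containment honours window kind and lifetime", {
  reg <- exclusion_registry()
  expect_false(is_excluded(reg, 150, 100))

  register_fragmentation(reg, 150, 100, 1e5, mode = "dew_box",
                         rt_tol = 30, mz_tol = 0.01)
  w <- registry_windows(reg)
  expect_equal(w$rt_lo, 100); expect_equal(w$rt_hi, 130)
  expect_equal(w$mz_lo, 149.99); expect_equal(w$mz_hi, 150.01)
  expect_true(is_excluded(reg, 150, 115))
  expect_false(is_excluded(reg, 150.02, 115))

  # expiry: pruned DEWs never match
  prune_dews(reg, 131)
  expect_false(is_excluded(reg, 150, 115))
})

test_that("phi consults carried windows only and takes the maximum", {
  reg <- exclusion_registry()
  # a within-injection DEW must not feed phi
  register_fragmentation(reg, 200, 50, 1e6, mode = "dew_box")
  expect_true(is.na(phi(reg, 200, 55)))

  # two carried windows at the same location: max intensity wins
  st <- roi_state(roi_params(min_intensity = 0))
  roi_update(st, 200, 1e4, 45)
  roi_update(st, 200, 1e5, 55)
  roi_record_frag(st, 1L, 46, 1e4)
  roi_record_frag(st, 1L, 56, 1e5)
  register_fragmentation(reg, 200, 46, 1e4, mode = "roi_box", roi_slot = 1L)
  advance_injection(reg, st, injection = 1L)
  expect_equal(phi(reg, 200, 50), 1e5)   # max over the RoI's events
  expect_true(is.na(phi(reg, 300, 50)))

  reg2 <- exclusion_registry()
  for (int in c(1e4, 1e5)) {
    stx <- roi_state(roi_params(min_intensity = 0))
    roi_update(stx, 500, int, 100)
    roi_record_frag(stx, 1L, 100, int)
    register_fragmentation(reg2, 500, 100, int, mode = "roi_box",
                           roi_slot = 1L)
    advance_injection(reg2, stx, injection = 1L)
  }
  expect_equal(phi(reg2, 500, 100), 1e5)
})

test_that("injection rollover accumulates carried windows monotonically", {
  reg <- exclusion_registry()
  seen <- 0L
  for (inj in 1:4) {
    register_fragmentation(reg, 100 + inj, 50, 1e4, mode = "dew_box",
                           carry = TRUE)
    advance_injection(reg, injection = inj)
    w <- registry_windows(reg)
    expect_gte(nrow(w), seen)
    seen <- nrow(w)
    expect_true(all(w$kind == "dew_box"))
  }
  expect_equal(seen, 4L)
  # carried windows from injection 1 are still active in injection 4
  expect_true(is_excluded(reg, 101, 55, include = "carried"))
})

test_that("within-injection DEWs are cleared at rollover", {
  reg <- exclusion_registry()
  register_fragmentation(reg, 150, 100, 1e5, mode = "dew_box")
  advance_injection(reg, injection = 1L)
  expect_false(is_excluded(reg, 150, 115))
})

test_that("carried RoI boxes honour the configured padding", {
  for (pads in list(c(0, 0), c(5, 0.02))) {
    reg <- exclusion_registry(rt_pad = pads[1], mz_pad = pads[2])
    st <- roi_state(roi_params(min_intensity = 0, mz_tol_unit = "da",
                               mz_tol = 0.05))
    roi_update(st, 149.995, 1e4, 95)
    roi_update(st, 150.005, 1e5, 110)
    roi_record_frag(st, 1L, 96, 1e4)
    register_fragmentation(reg, 150, 96, 1e4, mode = "roi_box", roi_slot = 1L)
    advance_injection(reg, st, injection = 1L)
    w <- registry_windows(reg)
    expect_equal(w$rt_lo, 95 - pads[1]); expect_equal(w$rt_hi, 110 + pads[1])
    expect_equal(w$mz_lo, 149.995 - pads[2])
    expect_equal(w$mz_hi, 150.005 + pads[2])
  }
})

test_that("queries agree with a brute-force scan over all windows", {
  set.seed(99)
  reg <- exclusion_registry()
  st <- roi_state(roi_params(min_intensity = 0, max_missed = 1000))
  # lay down a mixed population of windows
  for (i in 1:40) {
    mz <- runif(1, 100, 900); rt <- runif(1, 0, 300)
    register_fragmentation(reg, mz, rt, runif(1, 1e3, 1e6),
                           mode = "dew_box", rt_tol = 20, mz_tol = 0.05,
                           carry = TRUE)
  }
  for (i in 1:30) {
    mz <- runif(1, 100, 900); rt0 <- runif(1, 0, 280)
    roi_update(st, mz, 1e4, rt0)
    roi_update(st, mz + runif(1, 0, 0.02), 1e5, rt0 + runif(1, 5, 30))
    slot <- nrow(roi_snapshot(st))
    roi_record_frag(st, slot, rt0, runif(1, 1e3, 1e6))
    register_fragmentation(reg, mz, rt0, 1e4, mode = "roi_box",
                           roi_slot = slot)
  }
  advance_injection(reg, st, injection = 1L)
  for (i in 1:15) {
    register_fragmentation(reg, runif(1, 100, 900), runif(1, 0, 300),
                           runif(1, 1e3, 1e6), mode = "dew_box",
                           rt_tol = 20, mz_tol = 0.05)
  }
  w <- registry_windows(reg)
  w_dew <- w[w$kind == "dew", ]
  w_car <- w[w$kind != "dew", ]
  qmz <- runif(1000, 100, 900); qrt <- runif(1000, 0, 320)
  brute <- function(tbl, mz, rt) {
    vapply(seq_along(mz), function(i) {
      any(mz[i] >= tbl$mz_lo & mz[i] <= tbl$mz_hi &
          rt[i] >= tbl$rt_lo & rt[i] <= tbl$rt_hi)
    }, logical(1))
  }
  expect_identical(is_excluded(reg, qmz, qrt),
                   brute(w_dew, qmz, qrt) | brute(w_car, qmz, qrt))
  expect_identical(is_excluded(reg, qmz, qrt, include = "carried"),
                   brute(w_car, qmz, qrt))
  brute_phi <- vapply(seq_along(qmz), function(i) {
    hit <- qmz[i] >= w_car$mz_lo & qmz[i] <= w_car$mz_hi &
      qrt[i] >= w_car$rt_lo & qrt[i] <= w_car$rt_hi
    if (any(hit)) max(w_car$intensity[hit]) else NA_real_
  }, numeric(1))
  expect_identical(phi(reg, qmz, qrt), brute_phi)
})

test_that("registries round-trip through CSV", {
  reg <- exclusion_registry()
  register_fragmentation(reg, 150, 100, 1e5, mode = "dew_box", carry = TRUE)
  register_fragmentation(reg, 400, 200, 2e5, mode = "dew_box", carry = TRUE)
  advance_injection(reg, injection = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  reg2 <- read_registry(path)
  expect_equal(registry_windows(reg2), registry_windows(reg))
  qmz <- seq(149, 151, by = 0.001)
  expect_identical(is_excluded(reg2, qmz, rep(110, length(qmz))),
                   is_excluded(reg, qmz, rep(110, length(qmz))))
})
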