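test_that("dissection handles the identity and full-cover cases", {
  q <- rect(0, 2, 0, 2)

  d0 <- dissect(q)
  expect_equal(nrow(d0$pieces), 1L)
  expect_length(d0$pieces$owners[[1]], 0)
  expect_equal(d0$pieces$area, 4)
  expect_equal(non_overlap_proportion(d0), 1)

  d1 <- dissect(q, rect(0, 2, 0, 2, id = "b"))
  owned <- vapply(d1$pieces$owners, length, integer(1)) > 0
  expect_equal(sum(d1$pieces$area[owned]), 4)
  expect_equal(non_overlap_proportion(d1), 0)
})

test_that("partial overlap splits area as the rasterization oracle says", {
  q <- rect(0, 2, 0, 2)
  b <- rect(1, 3, 1, 3, id = "b")
  d <- dissect(q, b)
  uncov <- sum(d$pieces$area[vapply(d$pieces$owners, length, integer(1)) == 0])
  cov <- sum(d$pieces$area[vapply(d$pieces$owners, length, integer(1)) > 0])
  rr <- raster_regions(q, b, n = 500)
  expect_equal(uncov, 3)
  expect_equal(cov, 1)
  expect_equal(uncov, rr$uncovered, tolerance = 0.01)
  expect_equal(non_overlap_proportion(d), 0.75)
})

test_that("piece areas always sum to the query area (conservation)", {
  for (seed in 1:25) {
    cfg <- random_rect_config(seed)
    d <- dissect(cfg$query, cfg$others)
    expect_equal(sum(d$pieces$area), rect_area(cfg$query),
                 tolerance = 1e-9)
  }
})

test_that("non-overlap proportion matches the grid oracle on random sets", {
  for (seed in 101:130) {
    cfg <- random_rect_config(seed)
    d <- dissect(cfg$query, cfg$others)
    rr <- raster_regions(cfg$query, cfg$others, n = 500)
    expect_equal(non_overlap_proportion(d), rr$uncovered / rr$query_area,
                 tolerance = 0.01)
  }
})

test_that("adding an overlapping rectangle never raises the proportion", {
  for (seed in 201:215) {
    cfg <- random_rect_config(seed, max_others = 6)
    props <- vapply(0:nrow(cfg$others), function(k) {
      non_overlap_proportion(dissect(cfg$query, cfg$others[seq_len(k), ]))
    }, numeric(1))
    expect_true(all(diff(props) <= 1e-12))
  }
})

test_that("uncovered area matches closed-form inclusion-exclusion", {
  inter_area <- function(a, b) {
    max(0, min(a$rt_hi, b$rt_hi) - max(a$rt_lo, b$rt_lo)) *
      max(0, min(a$mz_hi, b$mz_hi) - max(a$mz_lo, b$mz_lo))
  }
  set.seed(42)
  for (rep in 1:10) {
    q <- rect(0, 3, 0, 3)
    k <- sample(2:3, 1)
    lo_rt <- runif(k, -1, 2.5); lo_mz <- runif(k, -1, 2.5)
    others <- rect(lo_rt, lo_rt + runif(k, 0.5, 2),
                   lo_mz, lo_mz + runif(k, 0.5, 2),
                   id = paste0("b", 1:k))
    # inclusion-exclusion of |q ∩ union(others)| (pairwise/triple clips)
    clip <- function(ix) {
      r <- list(rt_lo = max(q$rt_lo, max(others$rt_lo[ix])),
                rt_hi = min(q$rt_hi, min(others$rt_hi[ix])),
                mz_lo = max(q$mz_lo, max(others$mz_lo[ix])),
                mz_hi = min(q$mz_hi, min(others$mz_hi[ix])))
      max(0, r$rt_hi - r$rt_lo) * max(0, r$mz_hi - r$mz_lo)
    }
    subsets <- unlist(lapply(1:k, function(m) combn(k, m, simplify = FALSE)),
                      recursive = FALSE)
    covered <- sum(vapply(subsets, function(ix) {
      (-1)^(length(ix) + 1) * clip(ix)
    }, numeric(1)))
    expect_equal(non_overlap_proportion(dissect(q, others)),
                 (rect_area(q) - covered) / rect_area(q), tolerance = 1e-9)
  }
})

test_that("intensity region sum reduces to the raw intensity when alone", {
  d <- dissect(rect(0, 2, 0, 2))
  expect_equal(intensity_region_sum(d, 1000), 1000)
})

test_that("a dominating cover zeroes the intensity region sum", {
  d <- dissect(rect(0, 2, 0, 2), rect(-1, 3, -1, 3, id = "b"))
  expect_equal(intensity_region_sum(d, 1000, c(b = 1000)), 0)
  expect_equal(intensity_region_sum(d, 1000, c(b = 5000)), 0)
})

test_that("worked two-rectangle intensity region sum matches enumeration", {
  q <- rect(0, 2, 0, 2)
  b <- rect(1, 3, 1, 3, id = "b")
  d <- dissect(q, b)
  expect_equal(intensity_region_sum(d, 1000, c(b = 100)),
               1000^0.75 + 900^0.25, tolerance = 1e-12)
  expect_equal(intensity_region_sum(d, 1000, c(b = 100)),
               raster_region_sum(q, b, 1000, 100, n = 500),
               tolerance = 1e-3)
})

test_that("a single zero-intensity cover leaves the query intensity intact", {
  # sum over one combination: lambda^prop with prop = 1 (power-law split
  # of the exponent over a single piece)
  q <- rect(0, 2, 0, 2)
  d <- dissect(q, rect(-1, 3, -1, 3, id = "b"))
  expect_equal(intensity_region_sum(d, 1234, c(b = 0)), 1234)
  # and when the cover is partial, the two zero-modified terms multiply
  # back to lambda under the power law: lambda^p * lambda^(1-p) = lambda
  d2 <- dissect(q, rect(1, 3, 1, 3, id = "b"))
  terms <- c(1234^non_overlap_proportion(d2),
             1234^(1 - non_overlap_proportion(d2)))
  expect_equal(prod(terms), 1234, tolerance = 1e-9)
  expect_equal(intensity_region_sum(d2, 1234, c(b = 0)), sum(terms),
               tolerance = 1e-9)
})

test_that("degenerate zero-area queries are flagged and score as whole", {
  d <- dissect(rect(1, 1, 5, 5))
  expect_true(d$degenerate)
  expect_equal(non_overlap_proportion(d), 1)
  # covered degenerate query: modified intensity with prop 1
  d2 <- dissect(rect(1, 1, 5, 5), rect(0, 2, 4, 6, id = "b"))
  expect_true(d2$degenerate)
  expect_equal(non_overlap_proportion(d2), 1)
  expect_equal(intensity_region_sum(d2, 1000, c(b = 400)), 600)
  expect_equal(intensity_region_sum(d2, 1000, c(b = 2000)), 0)
})

test_that("invalid rectangles are rejected", {
  expect_error(rect(2, 1, 0, 1), "invalid rect")
  expect_error(rect(0, 1, 2, 1), "invalid rect")
  expect_error(dissect(rect(0, 1, 0, 1), tibble::tibble(rt_lo = 0)),
               "id")
})
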