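# Grid-rasterization oracle for rectangle dissection: covers the query with
# an n x n grid of cell centres and tallies, per subset of covering boxes,
# the total cell area. Independent of the package's sweep construction.
raster_regions <- function(query, others, n = 500) {
  rt <- seq(query$rt_lo, query$rt_hi, length.out = n + 1)
  mz <- seq(query$mz_lo, query$mz_hi, length.out = n + 1)
  rtc <- (rt[-1] + rt[-(n + 1)]) / 2
  mzc <- (mz[-1] + mz[-(n + 1)]) / 2
  cell <- diff(rt)[1] * diff(mz)[1]
  k <- nrow(others)
  key <- matrix(0, n, n)
  for (j in seq_len(k)) {
    cov <- outer(rtc >= others$rt_lo[j] & rtc <= others$rt_hi[j],
                 mzc >= others$mz_lo[j] & mzc <= others$mz_hi[j], `&`)
    key <- key + cov * 2^(j - 1)
  }
  counts <- table(as.vector(key))
  keys <- as.numeric(names(counts))
  members <- lapply(keys, function(v) {
    out <- integer()
    for (j in seq_len(k)) if (v %/% 2^(j - 1) %% 2 >= 1) out <- c(out, j)
    out
  })
  list(
    areas = as.numeric(counts) * cell,
    members = members,
    uncovered = if (any(keys == 0)) counts[[which(keys == 0)]] * cell else 0,
    query_area = (query$rt_hi - query$rt_lo) * (query$mz_hi - query$mz_lo)
  )
}

# Rasterized intensity region sum (the argument of the intensity
# non-overlap log), using the oracle's regions.
raster_region_sum <- function(query, others, lambda_query, lambda_others,
                              n = 500) {
  rr <- raster_regions(query, others, n)
  total <- 0
  for (i in seq_along(rr$areas)) {
    lam_max <- if (length(rr$members[[i]])) {
      max(lambda_others[rr$members[[i]]])
    } else 0
    lam <- lambda_query - lam_max
    if (lam > 0) total <- total + lam^(rr$areas[i] / rr$query_area)
  }
  total
}

# random rectangle configurations used by several property tests
random_rect_config <- function(seed, max_others = 10) {
  set.seed(seed)
  q <- rect(0, runif(1, 1, 5), 0, runif(1, 1, 5))
  k <- sample(0:max_others, 1)
  others <- rect(
    rt_lo <- runif(k, -1, 4), rt_lo + runif(k, 0.2, 3),
    mz_lo <- runif(k, -1, 4), mz_lo + runif(k, 0.2, 3),
    id = if (k) paste0("b", seq_len(k)) else character()
  )
  list(query = q, others = others)
}
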