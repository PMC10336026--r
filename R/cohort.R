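#' Configuration for a synthetic multi-sample chemical cohort
#'
#' Describes the ground truth a simulated experiment draws on: a set of
#' chemicals with Gaussian chromatographic peaks, split into chemicals
#' shared by every sample and chemicals unique to one sample, with
#' per-sample intensity factors. All randomness is fixed by `seed`.
#'
#' Defaults emulate a small-molecule (metabolomics) run on a
#' high-resolution instrument: m/z 70-1000, peaks eluting across a few
#' hundred seconds with widths of ~10 s, apex intensities log-normal
#' around 1e6 counts, and a minimum m/z spacing of twice the usual
#' isolation width so that ground truth is unambiguous under isolation.
#'
#' @param n_samples Number of samples.
#' @param n_shared Chemicals present in every sample.
#' @param n_unique Chemicals unique to each sample.
#' @param mz_range m/z range (Daltons).
#' @param rt_range Apex retention-time range (seconds).
#' @param intensity_meanlog,intensity_sdlog Log-normal apex intensity.
#' @param sigma_meanlog,sigma_sdlog Log-normal peak width (seconds).
#' @param factor_sdlog Log-normal spread of per-sample intensity factors
#'   (meanlog 0).
#' @param min_mz_spacing Minimum m/z separation between chemicals
#'   (Daltons); set to 0 to disable and allow chimeric selection.
#' @param truth_k Truth-box rt half-width in peak sigmas.
#' @param truth_mz_tol Truth-box m/z half-width (Daltons).
#' @param seed Integer seed fixing the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 1, n_shared = 300, n_unique = 0,
                          mz_range = c(70, 1000), rt_range = c(40, 400),
                          intensity_meanlog = log(1e6), intensity_sdlog = 1.2,
                          sigma_meanlog = log(9), sigma_sdlog = 0.25,
                          factor_sdlog = 0.3, min_mz_spacing = 1.4,
                          truth_k = 3, truth_mz_tol = 0.01, seed = 1) {
  stopifnot(n_samples >= 1, n_shared >= 0, n_unique >= 0,
            diff(mz_range) > 0, diff(rt_range) >= 0,
            truth_k > 0, truth_mz_tol > 0)
  n_total <- n_shared + n_samples * n_unique
  if (min_mz_spacing > 0 && n_total > 1 &&
      (n_total - 1) * min_mz_spacing >= diff(mz_range)) {
    stop("m/z range cannot hold ", n_total, " chemicals at spacing ",
         min_mz_spacing, call. = FALSE)
  }
  structure(list(n_samples = n_samples, n_shared = n_shared,
                 n_unique = n_unique, mz_range = mz_range,
                 rt_range = rt_range,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
                 factor_sdlog = factor_sdlog,
                 min_mz_spacing = min_mz_spacing,
                 truth_k = truth_k, truth_mz_tol = truth_mz_tol,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Uniform draw of n sorted values in [lo, hi] with pairwise spacing >= s:
# draw in the slack interval and shift by the cumulative spacing.
draw_spaced <- function(n, lo, hi, s) {
  if (n == 0L) return(numeric())
  slack <- (hi - lo) - (n - 1) * s
  sort(stats::runif(n, 0, slack)) + s * (seq_len(n) - 1) + lo
}

#' Generate a ground-truth cohort
#'
#' Draws the chemicals, their per-sample presence and intensity factors,
#' and the aligned truth-peak boxes (one box per chemical and sample where
#' it is present, spanning the apex plus/minus `truth_k` peak widths in rt
#' and `truth_mz_tol` in m/z, with the factor-scaled apex intensity
#' recorded). Alignment across samples is by construction: one chemical is
#' one aligned row. The same seed always reproduces the same cohort.
#'
#' @param cfg A [cohort_config()].
#' @return A list of class `dda_cohort`: `chemicals` (tibble: `chem_id`,
#'   `mz`, `apex_rt`, `apex_intensity`, `sigma`, `shape`), `sample_map`
#'   (tibble: `sample`, `chem_id`, `factor`), `truth_peaks` (tibble:
#'   `row_id`, `sample`, `rt_lo`, `rt_hi`, `mz_lo`, `mz_hi`,
#'   `apex_intensity`), and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_samples = 2, n_shared = 5,
#'                                      n_unique = 1, seed = 7))
#' nrow(coh$chemicals)   # 7
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  n_total <- cfg$n_shared + cfg$n_samples * cfg$n_unique
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  mz <- draw_spaced(n_total, cfg$mz_range[1], cfg$mz_range[2],
                    max(cfg$min_mz_spacing, 0))
  mz <- sample(mz)    # decouple m/z order from shared/unique assignment
  chem_id <- sprintf("C%04d", seq_len(n_total))
  chems <- tibble::tibble(
    chem_id = chem_id,
    mz = mz,
    apex_rt = stats::runif(n_total, cfg$rt_range[1], cfg$rt_range[2]),
    apex_intensity = stats::rlnorm(n_total, cfg$intensity_meanlog,
                                   cfg$intensity_sdlog),
    sigma = stats::rlnorm(n_total, cfg$sigma_meanlog, cfg$sigma_sdlog),
    shape = "gaussian"
  )
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  shared_ids <- chem_id[seq_len(cfg$n_shared)]
  presence <- dplyr::bind_rows(
    tidyr::expand_grid(sample = samples, chem_id = shared_ids),
    if (cfg$n_unique > 0) {
      uniq <- chem_id[cfg$n_shared + seq_len(cfg$n_samples * cfg$n_unique)]
      tibble::tibble(
        sample = rep(samples, each = cfg$n_unique),
        chem_id = uniq
      )
    }
  )
  presence$factor <- stats::rlnorm(nrow(presence), 0, cfg$factor_sdlog)

  truth <- presence |>
    dplyr::inner_join(chems, by = "chem_id") |>
    dplyr::transmute(
      row_id = .data$chem_id,
      sample = .data$sample,
      rt_lo = .data$apex_rt - cfg$truth_k * .data$sigma,
      rt_hi = .data$apex_rt + cfg$truth_k * .data$sigma,
      mz_lo = .data$mz - cfg$truth_mz_tol,
      mz_hi = .data$mz + cfg$truth_mz_tol,
      apex_intensity = .data$apex_intensity * .data$factor
    ) |>
    dplyr::arrange(.data$row_id, .data$sample)

  structure(list(chemicals = chems, sample_map = presence,
                 truth_peaks = truth, config = cfg),
            class = "dda_cohort")
}

#' @export
print.dda_cohort <- function(x, ...) {
  cat("<dda_cohort> ", nrow(x$chemicals), " chemicals, ",
      length(unique(x$sample_map$sample)), " sample(s), ",
      nrow(x$truth_peaks), " truth peaks\n", sep = "")
  invisible(x)
}

# save/restore .Random.seed so seeded generators do not disturb the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Model intensity of each chemical at retention time rt (vectorised over
# chemicals). `factor` scales apexes per sample. Empirical shapes (from
# resimulation) linearly interpolate their stored trace and are 0 outside.
chromatogram_at <- function(chems, rt, factor = 1) {
  out <- numeric(nrow(chems))
  g <- chems$shape == "gaussian"
  if (any(g)) {
    z <- (rt - chems$apex_rt[g]) / chems$sigma[g]
    out[g] <- chems$apex_intensity[g] * exp(-0.5 * z * z)
  }
  if (any(!g)) {
    for (i in which(!g)) {
      p <- chems$points[[i]]
      out[i] <- if (rt < p$rt[1] || rt > p$rt[length(p$rt)]) 0 else
        stats::approx(p$rt, p$int, xout = rt)$y
    }
  }
  out * factor
}

#' Convert a fullscan mzML into a resimulation chemical set
#'
#' Builds RoIs from the file's MS1 stream with the real-time tracker and
#' turns each RoI of at least `min_points` points into a chemical whose
#' chromatogram linearly interpolates the RoI's trace. Simulating a
#' fullscan-only run from the result and re-extracting RoIs recovers the
#' original apexes.
#'
#' @param path A readable mzML file containing MS1 scans.
#' @param roi [roi_params()] for the extraction (point storage is forced
#'   on).
#' @param min_points Minimum trace length for a RoI to become a chemical.
#' @return A chemicals tibble (`shape = "empirical"`, with a `points`
#'   list-column), usable wherever generated chemicals are.
#' @export
chemicals_from_fullscan <- function(path, roi = roi_params(), min_points = 2) {
  scans <- read_fullscan_mzml(path)
  if (!nrow(scans)) stop("no MS1 scans in ", path, call. = FALSE)
  roi$store_points <- TRUE
  st <- roi_state(roi)
  for (i in seq_len(nrow(scans))) {
    pk <- scans$peaks[[i]]
    roi_update(st, pk[, 1], pk[, 2], scans$rt[i])
  }
  idx <- which(st$n_pts >= min_points)
  if (!length(idx)) {
    return(tibble::tibble(chem_id = character(), mz = numeric(),
                          apex_rt = numeric(), apex_intensity = numeric(),
                          sigma = numeric(), shape = character(),
                          points = list()))
  }
  pts <- lapply(st$pts[idx], function(p) {
    tibble::tibble(rt = p$rt, int = p$int)
  })
  apex_i <- vapply(pts, function(p) which.max(p$int), integer(1))
  tibble::tibble(
    chem_id = sprintf("R%04d", seq_along(idx)),
    mz = vapply(seq_along(idx), function(j) {
      # intensity-weighted mean m/z of the trace
      p <- st$pts[[idx[j]]]
      sum(p$mz * p$int) / sum(p$int)
    }, numeric(1)),
    apex_rt = vapply(seq_along(pts), function(j) pts[[j]]$rt[apex_i[j]],
                     numeric(1)),
    apex_intensity = vapply(seq_along(pts), function(j) max(pts[[j]]$int),
                            numeric(1)),
    sigma = NA_real_,
    shape = "empirical",
    points = pts
  )
}
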