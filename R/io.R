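EVENT_LOG_VERSION <- "ddasim-events-v1"

#' Write scans to an mzML file
#'
#' Emits a valid, centroided mzML with MS levels, retention times, and
#' precursor isolation (target m/z, offsets, intensity) on MS2 scans.
#' Reading the file back reproduces scan counts, levels, retention times
#' and precursor targets exactly.
#'
#' @param scans A scan tibble (as returned by [run_injection()] with
#'   `return_scans = TRUE`): columns `ms_level`, `rt`, `precursor_mz`,
#'   `precursor_intensity`, `isolation_width`, `peaks` (list of two-column
#'   mz/intensity matrices). Must be clock-ordered.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scans, path) {
  n <- nrow(scans)
  if (n && is.unsorted(scans$rt)) {
    stop("scans must be clock-ordered by rt", call. = FALSE)
  }
  pk <- lapply(seq_len(n), function(i) {
    m <- scans$peaks[[i]]
    if (is.null(m) || !nrow(m)) {
      matrix(numeric(), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
    } else m
  })
  npk <- vapply(pk, nrow, integer(1))
  ms2 <- scans$ms_level == 2L
  if (n == 0L) {   # scalar columns do not recycle into an empty frame
    ms2 <- logical(); npk <- integer()
    scans <- tibble::tibble(ms_level = integer(), rt = numeric(),
                            precursor_mz = numeric(),
                            precursor_intensity = numeric(),
                            isolation_width = numeric())
  }
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(scans$ms_level), polarity = rep(1L, n),
    peaksCount = npk,
    totIonCurrent = vapply(pk, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = scans$rt,
    basePeakMZ = vapply(pk, function(m) if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(m) if (nrow(m)) max(m[, 2]) else 0, numeric(1)),
    collisionEnergy = as.numeric(ifelse(ms2, 25, NA_real_)),
    ionisationEnergy = rep(0, n),
    lowMZ = vapply(pk, function(m) if (nrow(m)) min(m[, 1]) else 0, numeric(1)),
    highMZ = vapply(pk, function(m) if (nrow(m)) max(m[, 1]) else 0, numeric(1)),
    precursorScanNum = rep(NA_integer_, n),
    precursorMZ = as.numeric(ifelse(ms2, scans$precursor_mz, NA_real_)),
    precursorCharge = as.integer(ifelse(ms2, 1L, NA_integer_)),
    precursorIntensity = as.numeric(ifelse(ms2, scans$precursor_intensity, NA_real_)),
    mergedScan = rep(NA_integer_, n), mergedResultScanNum = rep(NA_integer_, n),
    mergedResultStartScanNum = rep(NA_integer_, n), mergedResultEndScanNum = rep(NA_integer_, n),
    injectionTime = rep(0, n),
    filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = as.numeric(ifelse(ms2, scans$precursor_mz, NA_real_)),
    isolationWindowLowerOffset = as.numeric(ifelse(ms2, scans$isolation_width / 2, NA_real_)),
    isolationWindowUpperOffset = as.numeric(ifelse(ms2, scans$isolation_width / 2, NA_real_)),
    scanWindowLowerLimit = rep(NA_real_, n), scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(object = pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read the MS1 stream of an mzML file
#'
#' Yields MS1 scans in retention-time order (re-sorting with a warning if
#' the file is unordered); MS2 scans are skipped with a message reporting
#' how many were ignored.
#'
#' @param path An mzML file.
#' @return A scan tibble (columns as in [write_mzml()]) containing only
#'   MS1 scans.
#' @export
read_fullscan_mzml <- function(path) {
  scans <- read_mzml(path)
  n2 <- sum(scans$ms_level != 1L)
  if (n2) message("ignoring ", n2, " non-MS1 scan(s)")
  scans <- scans[scans$ms_level == 1L, , drop = FALSE]
  if (nrow(scans) && is.unsorted(scans$rt)) {
    warning("MS1 scans were not rt-ordered; re-sorting")
    scans <- scans[order(scans$rt), ]
  }
  scans
}

#' @rdname read_fullscan_mzml
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  h <- tryCatch({
    f <- mzR::openMSfile(path)
    on.exit(mzR::close(f), add = TRUE)
    hd <- mzR::header(f)
    pk <- if (nrow(hd)) mzR::peaks(f) else list()
    list(hd = hd, pk = pk)
  }, error = function(e) {
    stop("failed to read mzML ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  hd <- h$hd
  pk <- h$pk
  if (nrow(hd) == 1L && is.matrix(pk)) pk <- list(pk)
  tibble::tibble(
    ms_level = as.integer(hd$msLevel),
    rt = hd$retentionTime,
    precursor_mz = ifelse(hd$msLevel > 1L, hd$precursorMZ, NA_real_),
    precursor_intensity = ifelse(hd$msLevel > 1L, hd$precursorIntensity,
                                 NA_real_),
    isolation_width = ifelse(hd$msLevel > 1L,
                             hd$isolationWindowLowerOffset +
                               hd$isolationWindowUpperOffset, NA_real_),
    peaks = lapply(pk, function(m) {
      colnames(m) <- c("mz", "intensity")
      m
    })
  )
}

#' Write / read a fragmentation-event log
#'
#' CSV with a versioned header comment so evaluation stays decoupled from
#' simulation. Event values are written in full precision; a written log
#' read back compares equal.
#'
#' @param events Event tibble (see [run_experiment()]).
#' @param path CSV file path.
#' @return `write_events()`: `path` invisibly; `read_events()`: the event
#'   tibble.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  writeLines(paste0("# ", EVENT_LOG_VERSION), con)
  close(con)
  readr::write_csv(events, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    injection = readr::col_integer(),
                    sample = readr::col_character(),
                    cycle = readr::col_integer(),
                    roi = readr::col_integer(),
                    .default = readr::col_double()))
}

#' Write / read an aligned peaklist
#'
#' The native dialect is one row per (aligned row, sample) box:
#' `row_id, sample, rt_lo, rt_hi, mz_lo, mz_hi, apex_intensity`, with rt
#' in seconds. `read_peaklist()` also understands an MZMine-2-style
#' aligned export (`format = "mzmine2"`): a `row ID` column plus
#' per-sample groups `<sample> Peak m/z min` / `m/z max` / `RT start` /
#' `RT end` / `height`. Because MZMine exports retention time in minutes
#' while mzML carries seconds, the rt unit must be stated explicitly.
#'
#' @param peaks Peaklist tibble (native columns).
#' @param path CSV file path.
#' @param format `"native"` or `"mzmine2"`.
#' @param rt_unit `"seconds"` or `"minutes"`; values are converted to
#'   seconds on read.
#' @return `write_peaklist()`: `path` invisibly; `read_peaklist()`: a
#'   native-dialect peaklist tibble with rt in seconds.
#' @export
write_peaklist <- function(peaks, path) {
  readr::write_csv(peaks, path)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path, format = c("native", "mzmine2"),
                          rt_unit = c("seconds", "minutes")) {
  format <- match.arg(format)
  rt_unit <- match.arg(rt_unit)
  mult <- if (rt_unit == "minutes") 60 else 1
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (format == "native") {
    req <- c("row_id", "sample", "rt_lo", "rt_hi", "mz_lo", "mz_hi",
             "apex_intensity")
    if (!all(req %in% names(df))) {
      stop("native peaklist lacks columns: ",
           paste(setdiff(req, names(df)), collapse = ", "), call. = FALSE)
    }
    out <- tibble::as_tibble(df)
    out$rt_lo <- out$rt_lo * mult
    out$rt_hi <- out$rt_hi * mult
    out$row_id <- as.character(out$row_id)
    return(out)
  }
  # MZMine-2 aligned export: wide, one column group per sample
  id_col <- grep("^row ?ID$", names(df), ignore.case = TRUE, value = TRUE)
  if (!length(id_col)) stop("mzmine2 peaklist lacks a 'row ID' column",
                            call. = FALSE)
  grp <- regmatches(names(df),
                    regexec("^(.*) Peak m/z min$", names(df)))
  samples <- vapply(grp[lengths(grp) == 2], `[`, character(1), 2)
  if (!length(samples)) {
    stop("mzmine2 peaklist has no '<sample> Peak m/z min' columns",
         call. = FALSE)
  }
  rows <- lapply(samples, function(s) {
    cols <- paste0(s, c(" Peak m/z min", " Peak m/z max",
                        " Peak RT start", " Peak RT end", " Peak height"))
    if (!all(cols %in% names(df))) {
      stop("mzmine2 peaklist lacks columns for sample ", s, call. = FALSE)
    }
    sub <- df[, c(id_col, cols)]
    names(sub) <- c("row_id", "mz_lo", "mz_hi", "rt_lo", "rt_hi",
                    "apex_intensity")
    sub$sample <- s
    sub[stats::complete.cases(sub), ]
  })
  out <- dplyr::bind_rows(rows)
  tibble::tibble(
    row_id = as.character(out$row_id), sample = out$sample,
    rt_lo = out$rt_lo * mult, rt_hi = out$rt_hi * mult,
    mz_lo = out$mz_lo, mz_hi = out$mz_hi,
    apex_intensity = out$apex_intensity
  )
}

#' Write / read an experiment configuration
#'
#' A human-readable YAML round trip of the controller configuration,
#' schedule and cohort settings, so an experiment is fully described by
#' one file.
#'
#' @param cfg A [controller_config()].
#' @param schedule An [injection_schedule()].
#' @param cohort_cfg A [cohort_config()] (optional).
#' @param path YAML file path.
#' @param seed,extras Additional scalar settings stored alongside.
#' @return `write_experiment_config()`: `path` invisibly;
#'   `read_experiment_config()`: a list with elements `cfg`, `schedule`,
#'   `cohort_cfg` (or `NULL`), `seed`, `extras`.
#' @export
write_experiment_config <- function(cfg, schedule, path, cohort_cfg = NULL,
                                    seed = 1, extras = list()) {
  obj <- list(
    controller = unclass(cfg)[setdiff(names(cfg), c("dew", "roi"))],
    dew = unclass(cfg$dew),
    roi = unclass(cfg$roi),
    schedule = unclass(schedule),
    cohort = if (!is.null(cohort_cfg)) unclass(cohort_cfg),
    seed = as.integer(seed),
    extras = extras
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  obj <- yaml::read_yaml(path)
  dew <- do.call(dew_config, obj$dew)
  roi <- do.call(roi_params, obj$roi)
  cfg <- do.call(controller_config,
                 c(obj$controller, list(dew = dew, roi = roi)))
  schedule <- do.call(injection_schedule, obj$schedule)
  cohort_cfg <- if (!is.null(obj$cohort)) do.call(cohort_config, obj$cohort)
  list(cfg = cfg, schedule = schedule, cohort_cfg = cohort_cfg,
       seed = obj$seed, extras = obj$extras)
}
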