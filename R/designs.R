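#' Canonical simulated experiment designs
#'
#' The package's two reference designs for benchmarking fragmentation
#' strategies, used throughout the documentation, the test suite and the
#' acceptance script.
#'
#' `design_single_sample()` is a multi-injection, single-sample design:
#' one mixture of `n_chemicals` chemicals injected `n_injections` times.
#' With no retention-time noise it isolates the effect of carrying
#' exclusion state across injections: plain TopN gains nothing after the
#' first pass, while multi-sample strategies keep collecting.
#'
#' `design_multi_sample()` is a samples-times-repeats design (default 6
#' samples, 4 repeats, injected round-robin) with partial overlap in
#' chemicals: `n_shared` chemicals common to every sample plus `n_unique`
#' private to each, with log-normal per-sample intensity factors.
#'
#' Both use the default instrument timing (0.59 s MS1, 0.19 s MS2) and a
#' compressed elution window (peaks over 40-130 s, 150 s acquisition).
#' The compression reproduces, at desk scale, the scarcity that makes
#' scan prioritisation matter on real complex mixtures: the number of
#' co-eluting peaks above the scheduling threshold comfortably exceeds
#' the MS2 slots a duty cycle offers, so a strategy must spend scans well
#' and plain TopN cannot exhaust a sample in one pass.
#'
#' @param n_injections Number of injections of the single sample.
#' @param n_chemicals Size of the single-sample mixture.
#' @param n_samples,repeats Multi-sample design shape.
#' @param n_shared,n_unique Shared/private chemical counts per sample.
#' @param seed Cohort seed.
#' @return A list with `cohort_cfg` (a [cohort_config()]) and `schedule`
#'   (an [injection_schedule()]).
#' @export
design_single_sample <- function(n_injections = 10, n_chemicals = 300,
                                 seed = 1) {
  list(
    cohort_cfg = cohort_config(n_samples = 1, n_shared = n_chemicals,
                               n_unique = 0, rt_range = c(40, 130),
                               seed = seed),
    schedule = injection_schedule(rep("S01", n_injections), max_rt = 150)
  )
}

#' @rdname design_single_sample
#' @export
design_multi_sample <- function(n_samples = 6, repeats = 4,
                                n_shared = 300, n_unique = 50, seed = 1) {
  samples <- sprintf("S%02d", seq_len(n_samples))
  list(
    cohort_cfg = cohort_config(n_samples = n_samples, n_shared = n_shared,
                               n_unique = n_unique, rt_range = c(40, 130),
                               seed = seed),
    schedule = injection_schedule(interleave_samples(samples, repeats),
                                  max_rt = 150)
  )
}
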