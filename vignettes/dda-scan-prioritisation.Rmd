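---
title: "Scan prioritisation for multi-sample DDA: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scan prioritisation for multi-sample DDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddasim)
```

## The problem

In data-dependent acquisition (DDA) LC-MS/MS, the instrument alternates
survey (MS1) scans with fragmentation (MS2) scans. After each MS1 scan the
controller may schedule up to *N* MS2 scans, each isolating one precursor.
Every choice has an opportunity cost: a scan spent refragmenting an abundant
ion is a scan not spent on a peak that has no spectrum yet. In
multi-injection, multi-sample experiments the same abundant ions elute in
every injection, so a naive TopN controller wastes a large share of its duty
cycle on material it has already fragmented.

`ddasim` implements a family of scan-prioritisation strategies that share
one parametric scoring function, together with a virtual instrument to run
them on, a seeded generator of ground-truth mixtures, and the two metrics
used to compare strategies: cumulative **peak coverage** (fraction of picked
peaks with at least one matching fragmentation event) and cumulative
**intensity coverage** (fraction of total peak apex intensity at which
spectra were acquired — a proxy for spectral quality).

## The scoring function

All strategies rank the candidates visible in the latest MS1 scan by

$$ s(c) = w_{ex}(c) \cdot \mathbb{1}[\lambda_c \ge \lambda_{min}] \cdot \mathrm{core}(c), $$

and schedule the top `N` candidates with $s > 0$. The three terms:

* $w_{ex}$ — the exclusion weight. For the non-RoI strategies this is the
  classic 0/1 dynamic-exclusion-window (DEW) indicator: 0 if the precursor
  sits inside an active exclusion box. For RoI-based strategies the rule is
  tied to the region of interest itself (a RoI may not be refragmented
  within `rt_tol` seconds of its last fragmentation), and the hard
  indicator can be replaced by a *SmartRoI* or *WeightedDEW* weight (see
  below).
* $\mathbb{1}[\lambda \ge \lambda_{min}]$ — a minimum-intensity gate;
  spectra acquired below a few thousand counts are rarely identifiable.
* $\mathrm{core}$ — what distinguishes the strategies:

| strategy | core on $\ln\lambda$ | carried between injections |
|---|---|---|
| `topn` | $\ln\lambda$ | nothing |
| `topn_exclusion` | $\ln\lambda$ | its DEW boxes |
| `topn_roi` | $\ln\lambda$ | nothing |
| `topn_exclusion_roi` | $\ln\lambda$ | DEW-box geometry |
| `hard_roi_exclusion` | $\ln\lambda$ | fragmented-RoI boxes (hard) |
| `intensity_roi_exclusion` | $\max(0,\ln\lambda-\ln\varphi)$ | fragmented-RoI boxes + intensity |
| `non_overlap` | $\mathrm{prop}(r)\cdot\ln\lambda$ | fragmented-RoI boxes + area |
| `intensity_non_overlap` | $\max(0, \ln\sum_B \max(0,\lambda_{B})^{p_B})$ | boxes + area + intensity |

Here $\varphi$ is the maximum intensity of any carried box containing the
precursor (`NA` → the log term is 0, i.e. the intensity is unmodified);
$\mathrm{prop}(r)$ is the fraction of the candidate RoI's rectangle not
covered by carried boxes; and the intensity non-overlap sum runs over the
distinct combinations $B$ of carried boxes overlapping the candidate, each
contributing its *modified intensity* $\lambda_B = \lambda - \max_{b \in B}
\lambda_b$ raised to the combination's proportional area $p_B$. With no
overlap at all the sum collapses to $\lambda^1$ and the score to
$\ln\lambda$ — every strategy reduces to TopN in the absence of exclusion
state, which the test suite asserts.

Two semantics follow the published framework deliberately: the hard
indicator of the intensity strategies consults only within-injection state,
while $\varphi$ consults only carried (between-injection) windows; and for
iterative exclusion (`topn_exclusion`) the carried objects are the DEW
boxes themselves with their expiry stripped.

## Geometry

The non-overlap scores require dissecting a query rectangle in
(rt, m/z) space against a set of covering rectangles into interior-disjoint
pieces labelled by exactly which boxes cover them. The kernel
(`dissect()`) cuts the query along every box boundary into grid cells and
aggregates cells by owner set. Only the piece/owner contract matters, not
the particular cut structure: piece areas always sum to the query area
(asserted to 1e-9 relative), and the per-combination areas are checked
against an independent 500×500 grid-rasterization oracle in the tests.
Numerical conventions: intervals are closed; boundary-touching rectangles
share zero area and are treated as non-overlapping (area scores are
unaffected by measure-zero sets); zero-area owner combinations are dropped
(they would contribute $\lambda^0 = 1$ spuriously); a non-positive modified
intensity contributes 0 (a negative base under a fractional exponent is
undefined); and a region sum $\le 1$ gives score 0, consistent with
"schedule only scores above zero". A degenerate zero-area query (a RoI seen
in a single scan) is scored with proportion 1 — for the intensity variant
this means $\max(0, \lambda - \max_b \lambda_b)$ over the boxes containing
the point, so a fresh candidate under a brighter carried box still scores 0.

## RoI tracking and exclusion weights

RoIs are built from streaming MS1 points in the centwave style: a point
extends the nearest live RoI within an m/z tolerance (default 10 ppm
against the RoI's last point) or seeds a new one; RoIs missing more than
`max_missed` (default 2) consecutive scans are closed. Ties are broken
deterministically: nearest last-point m/z, then the lower-m/z RoI; a RoI
accepts at most one point per scan. RoIs are extended to the right in
retention time as data arrives, and all exclusion decisions use the bounds
*at query time*, not the final bounds — except carried boxes, which are
registered from final bounds at the injection rollover.

The within-injection refragmentation rule comes in three schemes
(`dew_config()`):

* **plain** — excluded for `rt_tol` seconds (default 15 s) after a
  fragmentation;
* **weighteddew** — weight 0 until `t0`, rising linearly to 1 at `rt_tol`,
  so a recently fragmented but brightening RoI re-enters the ranking
  gradually;
* **smartroi** — re-enabled when the intensity has risen by
  `intensity_increase_factor` (default 10) over the minimum seen since the
  fragmentation, when it falls below `drop_fraction` (default 0.01) of the
  intensity at fragmentation, or after `reset_length` (default 100 s).
  The triggers are evaluated against the RoI's current state at query
  time; the running minimum is maintained as points arrive.

The exact published forms of these two weights live in supplementary
material that prints only their intent, so the state machine above is this
package's own formulation of the prior-work semantics, with every trigger
exposed as a parameter. Non-RoI strategies always use plain DEW boxes; the
weight substitution applies where exclusion is RoI-tied.

## The virtual instrument

`run_injection()` advances a clock through duty cycles: one MS1 scan
(0.59 s) followed by the controller's ≤ N MS2 scans (0.19 s each) — the
fixed scan lengths make simulated runs exactly reproducible. MS1 intensities
are each chemical's chromatogram evaluated at the scan's clock time. The
MS2 precursor intensity is the most intense model point within the
isolation window evaluated at the *MS2 scan's own* clock time: sampling at
execution rather than at the triggering survey scan keeps intensity-based
exclusion honest about what the instrument would actually deliver (the
alternative convention is a one-line change and affects logged intensities
by at most one duty cycle of chromatographic drift). MS2 spectra carry
deterministic placeholder fragments purely so the mzML output is
well-formed; fragment content plays no role in scoring.

Two noise knobs, both off-by-default philosophies stated explicitly:

* retention time carries **no** jitter by default, so repeated injections
  of one sample are identical — this isolates the effect of exclusion
  carryover (plain TopN is exactly flat after its first pass) and mirrors
  the deterministic baseline under which the strategies were originally
  compared in simulation; `rt_jitter` enables per-injection scatter for
  robustness experiments.
* the mass axis carries ppm-scale scatter (`mz_noise_ppm`, default 2 ppm
  s.d.), as on a real high-resolution instrument. Intensities and
  retention times are untouched, so scheduling decisions are unaffected,
  but RoIs acquire a genuine m/z extent. Without it every RoI rectangle
  would be a zero-width line in m/z and the area-overlap scores would
  degenerate to their point-containment counterparts.

## The synthetic cohort

`generate_cohort()` draws chemicals with Gaussian chromatograms: m/z
uniform over 70–1000 Da with a minimum spacing of 1.4 Da (twice the 0.7 Da
isolation width, so ground truth is unambiguous under isolation —
disable it to study chimeric selection); apex intensities log-normal
(median 1e6 counts, $\sigma_{\log} = 1.2$, so a realistic tail of dim
peaks hovers near the 5000-count scheduling threshold); peak widths
log-normal around 9 s. Multi-sample cohorts contain shared chemicals
(present in every sample) and per-sample unique chemicals, with log-normal
per-sample intensity factors ($\sigma_{\log} = 0.3$) standing in for
biological variation. Truth boxes span the apex ± 3σ in rt (99.7% of the
profile, mimicking picked-peak bounds) and ± 0.01 Da in m/z, and one
chemical is one aligned row — alignment across samples is by construction,
standing in for MZMine alignment.

What the generator does **not** emulate: isotope envelopes, adducts,
chimeric co-isolation, peak-shape asymmetry, retention-time drift between
samples, and electronic noise. Passing tests therefore demonstrate the
*logic* of the strategies — who gets excluded, what is carried over, how
the metrics rank the methods — under clean conditions, not performance on
real data.

## The canonical designs

The packaged designs (`design_single_sample()`, `design_multi_sample()`)
are the fixtures every directional claim is tested on:

* **single-sample ×10** — 300 chemicals injected 10 times, N = 10;
* **6×4 multi-sample** — 6 samples × 4 repeats injected round-robin
  (1-2-3-4-5-6-1-2-…), 300 shared + 50 unique chemicals per sample.

Both compress elution into 40–130 s with a 150 s acquisition window. The
compression is the package's chosen way of reproducing, at a size a laptop
can simulate in minutes, the *scarcity regime* of real complex mixtures:
what matters for scan prioritisation is the ratio of co-eluting
above-threshold peaks to available MS2 slots per duty cycle, and with ~350
concurrent peaks against 10 slots per 2.49 s cycle a single pass cannot
exhaust a sample (TopN plateaus near 75–79% coverage), so strategies
genuinely compete. With a sparse elution profile every strategy saturates
and the comparison is vacuous.

On these designs the packaged experiments reproduce the qualitative
findings the strategy family was designed around, each asserted by the
test suite: plain TopN is flat from injection 2 onward; hard RoI exclusion
dominates TopN everywhere and sweeps ≥95% of reachable peaks (apex above
the scheduling threshold) by injection 10; the intensity strategies keep
gaining intensity coverage after their peak coverage has plateaued; and
intensity non-overlap attains the highest final intensity coverage of all
strategies in both designs while every multi-sample strategy beats TopN on
final coverage.

## Evaluation metrics

The published description of the two metrics defers their exact formulas
to supplementary material, so the package adopts and documents canonical
definitions: a peak row is covered after injection *k* if any event in
injections ≤ *k*, in a sample where the row has a box, falls inside that
box; intensity coverage is $\sum_r \min(\text{best matched intensity}_r,
\text{apex}_r) / \sum_r \text{apex}_r$ with the best intensity taken over
all matched events so far. Capping at the apex bounds the metric by 1 even
when simulation sampling exceeds the picked apex; a row present in several
samples is covered by a match in any of them and its apex is the maximum
over its per-sample boxes. Any alternative metric can be computed from the
same event logs behind the same report type.

## Known limitations

* No modelling of ion accumulation (AGC), chimeric isolation, or
  instrument-control latency; scan durations are constants.
* The SmartRoI/WeightedDEW semantics are this package's reconstruction of
  prior-work behaviour, not a byte-level reimplementation.
* Coverage evaluation assumes the aligned peaklist's boxes are truthful;
  with real picked peaks the metrics inherit the peak-picker's quirks.
* The resimulation importer (`chemicals_from_fullscan()`) interpolates RoI
  traces linearly and drops sub-threshold tails, so very low, wide peaks
  round-trip with reduced apexes.
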