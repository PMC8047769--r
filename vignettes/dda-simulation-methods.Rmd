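---
title: "Simulating and bounding data-dependent acquisition: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and bounding data-dependent acquisition: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddasim)
```

`ddasim` is a testbed for data-dependent acquisition (DDA) logic: it
simulates an LC-MS instrument scanning a mixture of chemicals, lets
acquisition controllers decide what to fragment, and scores the outcome
against ground truth. This vignette documents the models behind each
stage, the parameters that matter, and the design decisions taken where
the problem is genuinely open — so that users know exactly what a
passing simulation does and does not demonstrate about real data.

## The chromatographic model

Each chemical ion is a Gaussian chromatographic peak

$$ I(t) = I_\max \exp\!\left(-\frac{(t - t_\text{apex})^2}{2\sigma^2}\right), $$

observed at its exact m/z. A Gaussian was chosen because it gives
closed-form detection-floor crossings — the ground-truth bounding box of
a peak is $t_\text{apex} \pm \sigma\sqrt{2\ln(I_\max/F)}$ for floor $F$
— which lets tests verify boxes analytically. Any unimodal shape would
serve; the intensity function is isolated behind `intensity_at()` so the
shape can be swapped without touching controllers or evaluation.

Generator defaults (`generate_mixture()`):

| parameter | default | why |
|---|---|---|
| m/z range | 70–1000 Th | a typical positive-mode full-scan window |
| apex intensity | log-uniform $10^4$–$10^7$ | complex extracts span several orders of magnitude; log-uniform makes "less-abundant ions" the norm, not the exception |
| peak width σ | uniform 5–15 s | peak FWHM of roughly 12–35 s, typical of HILIC gradients |
| box m/z half-width | 0.01 Th | narrow centroided boxes; twice the typical centroiding error |
| detection floor | $5 \times 10^3$ | equals the controllers' default minimum fragmentation intensity, so MS1 peak lists, boxes and matching-graph edges are mutually consistent |

The generator deliberately omits isotope patterns, adducts, chimeric
isolation and mass error: controllers here never exploit those features,
so adding them would only blur attribution when two controllers differ.
An optional `n_noise` parameter adds unpicked distractor signals (they
appear in survey scans but in no bounding box), and
`scan_timing_model(jitter_sd =)` adds Gaussian scan-time jitter to
emulate run-to-run variability; both are off by default so that every
run is exactly reproducible. Consequently, a coverage difference in this
simulator shows a difference in *acquisition logic* under clean,
unimodal, well-separated-in-m/z signals — it does not by itself
demonstrate robustness to isotopologue clutter, centroiding errors, or
detector saturation on real spectra.

## The virtual instrument

The event loop (`run_acquisition()`) keeps a queue of pending scans,
initially one MS1 survey scan at $t = 0$. Executing an MS1 scan
synthesizes the peak list (all chemicals at or above the detection
floor, sorted by m/z), hands it to the controller, and queues the
returned MS2 requests together with the next MS1 scan. The clock
advances by a fixed duration per scan level.

On real hardware the time between consecutive scan starts folds
together acquisition and the controller's processing; the simulator
adopts that folded duration directly. Defaults are per controller —
0.54 s (full-scan), 0.56 s (TopN), 0.61 s (WeightedDEW), 0.68 s
(SmartROI) MS1; 0.20 s MS2 — reflecting that ROI tracking costs the
most processing and that MS2 scans, acquired at much lower resolution,
are several times faster than survey scans. All are configurable.

Two semantics deserve explicit statement:

* **Run end.** A scan executes only if it *finishes* by `run_length`
  (with $10^{-9}$ s slack for floating-point accumulation). This makes
  the simulated run, the idealized schedule and step-by-step counting
  agree exactly.
* **Shifted scheduling.** With `shift = k`, the plan after each MS1 scan
  is: $n-k$ MS2 scans, the next MS1 scan, then the remaining $k$ MS2
  scans (still attributed to the earlier survey scan). On hardware this
  overlaps controller processing with acquisition so the instrument
  never idles. In the folded-time simulator the benefit cannot
  materialize as extra scans — the durations already include
  processing — so shifting reorders execution and slightly advances MS1
  times within each cycle. The simulator therefore demonstrates the
  *correctness* of shifted scheduling (causality, duty-cycle structure),
  while its throughput benefit is a hardware property. Cycles with fewer
  than $k$ requests defer what they have.

## Controllers

All controllers share one contract — initialize per-run state, react to
each completed MS1 scan with at most $N$ MS2 requests — and one
deterministic ranking: priority descending, ties toward higher m/z,
then earlier peak index. The fixed tie-break makes every run exactly
reproducible.

**TopN** requests the $N$ most intense peaks at or above
`min_intensity`, excluding any m/z (within 10 ppm) fragmented at most
$t_0$ seconds ago. The boundary is inclusive: at exactly
$t - t_f = t_0$ the ion is still excluded.

**WeightedDEW** replaces the binary exclusion with
$w = 0$ for $t - t_f \le t_0$, rising linearly to $1$ at $t_1$, and
ranks by intensity $\times$ weight; never-fragmented ions have weight 1,
and only strictly positive priorities are eligible. With $t_1 = t_0$
this is provably the same selection as TopN, and the test suite asserts
scan-for-scan identical logs across ten mixtures. Defaults
$t_0 = 15$ s, $t_1 = 120$ s are the grid-search optimum on complex
extracts. When a selected ion already has an exclusion record, the
record is overwritten (rather than appended), so "most recent
fragmentation" is always well defined.

**SmartROI** tracks regions of interest: each survey-scan peak extends
the active ROI with the nearest last m/z within 10 ppm (greedy
assignment in order of increasing m/z distance, ties toward lower m/z;
one peak per ROI per scan), unmatched peaks at or above the creation
threshold seed new ROIs, and unextended ROIs are discarded permanently.
An active ROI is *available* for fragmentation iff its current intensity
is at least `min_intensity` **and** it was never fragmented, or has
risen by a factor $\alpha$ over its intensity at last fragmentation, or
has fallen to a fraction $\beta$ of its maximum since that
fragmentation. "Dropped by a factor β" is implemented as
$I \le \beta \cdot \max$; with the default $\beta = 0.1$ an ROI re-arms
once it has decayed to 10 % of its post-fragmentation maximum — the
mechanism that catches a second chromatographic peak inside the same
ROI. Evaluating the floor rule before 3a/3b reproduces the intended
interplay: an ROI that decays below the floor becomes available via 3b
but only fires once it rises above the floor again. Defaults
$\alpha = 1000$, $\beta = 0.1$ are the grid-search optimum; the
degenerate limits ($\alpha = \infty$, $\beta = 0$: fragment each ROI at
most once) are tested explicitly.

The tolerances (10 ppm), the ROI-creation threshold (= the
fragmentation floor) and whether an ROI may absorb several peaks per
scan (it may not) are not dictated by the method definitions; all are
exposed as configuration with the stated defaults.

## The theoretical optimum

How many peaks could *any* DDA controller have fragmented? Build the
idealized schedule (MS1 followed by $N$ MS2 slots, repeated, at the mean
scan durations), then a bipartite graph between MS2 slots and bounding
boxes with an edge when (i) the slot's time lies inside the box's RT
bounds, (ii) the immediately preceding MS1 scan does too, and (iii) the
box's intensity at that MS1 scan is at least the fragmentation floor.
All time comparisons are inclusive at both endpoints. A maximum matching
— computed with Hopcroft–Karp over deterministically ordered adjacency
lists, so the matching itself (not only its size) is reproducible — is
the optimum. The implementation is validated against exhaustive
enumeration on 200 random small graphs and cross-checked against
igraph's independent matching routine.

The bound requires knowing the whole run in advance, so it is a
benchmark, not a strategy. For any simulated run, the coverage in which
each event credits at most one box never exceeds the maximum matching
computed on that run's *realized* schedule — each covered box consumes
a distinct MS2 slot, and the corresponding (slot, box) pairs are edges
of the graph. The default coverage credits an event to *every* box it
falls into (overlaps are counted as covered), which can in principle
exceed the slot bound when boxes overlap in both m/z and RT; a
single-credit mode (`unique_assignment = TRUE`) is available and is
what the bound theorem governs.

## Evaluation choices

*Coverage* is the number of distinct boxes containing at least one
fragmentation event; *efficiency* is coverage divided by **all** MS2
scans, including those that hit no box. Events are stamped with the MS2
scan's own start time by default (`event_time = "source_ms1"` switches
to the triggering survey scan's time) — the distinction only matters for
events near a box's RT edge, and neither convention is canonical.
Reports print efficiency to two decimals; the raw ratio is stored, and
`efficiency * n_ms2 == coverage` holds exactly before rounding.

`grid_search()` runs one simulation per grid point with identical
mixture, timing and seed, sequentially, and breaks score ties toward the
earlier grid point — deterministic by construction.

## Problem sizes and degenerate inputs

The shipped test suite exercises: hand-stepped duty cycles on two-
to three-chemical mixtures; 50–150-chemical mixtures for controller
properties, the matching bound (five seeds, five controllers) and
byte-identical determinism; 6×6 to 8×8 random graphs against the
enumeration oracle (200 instances); and one 1000-chemical mixture
compressed into 500 s — dozens of peaks coeluting per duty cycle —
where SmartROI and WeightedDEW both out-cover TopN at matched $N$ and
floor. These sizes keep the whole suite under a minute while still
producing thousands-of-scans runs; all scale linearly if larger studies
are wanted.

Degenerate inputs are defined rather than rejected wherever a
definition exists: empty mixtures, empty request lists (MS1-only duty
cycles), `shift` larger than the request count (clamped), zero-edge
graphs, and schedules shorter than one MS1 scan (empty, with a warning)
are all exercised in tests. Genuinely contradictory inputs — degenerate
ranges, MS2 counts of zero in the efficiency denominator, scans outside
the run — raise errors.

## Known limitations

* Fragment spectra are not simulated: MS2 scans carry precursor
  identity only, so spectral quality, chimeric isolation and
  collision-energy effects are out of scope.
* The folded timing model cannot express true acquisition/processing
  concurrency (see shifted scheduling above), automatic gain control,
  or instrument-side parallelization.
* ROI tracking implements live greedy matching only — no smoothing,
  peak-shape fitting, or prediction of whether an ROI will become a
  picked peak.
* The optimum is unweighted: it maximizes the count of fragmented
  peaks, not intensity-weighted value or spectral quality.
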