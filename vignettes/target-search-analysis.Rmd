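---
title: "Models and methods: single-molecule target search on DNA and nucleosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: single-molecule target search on DNA and nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfsearch)
```

This vignette documents the models implemented in `tfsearch`, the parameter
conventions and defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The scientific setting

A sequence-specific transcription factor in solution finds a short cognate
motif (here the GAGA-factor consensus `GAGAG`; overlapping copies such as
`GAGAGAG` count as two sites) on DNA that may be wrapped into a nucleosome.
Two search modes compete: *3D diffusion* — dissociation and re-association
at an uncorrelated position — and *1D sliding* — translocation along the
duplex without full dissociation. Single-molecule FRET reports which site
the factor occupies frame by frame: a Cy3-labeled factor binding within
nanometers of a Cy5- or Cy7-labeled site converts donor emission into
acceptor emission. On optical-tweezers tethers, a labeled factor is instead
tracked in confocal kymographs and its mobility summarized by a diffusion
coefficient.

## Templates, SHL coordinates and accessibility

Coordinates are 0-based and half-open throughout. A nucleosome core occupies
147 bp centred on the dyad; one superhelical location (SHL) spans
73/7 ≈ 10.43 bp, so SHL ±7 falls on the outermost core base pairs. `shl_of()`
reports SHL to the nearest 0.5 and returns `NA` (linker) outside the core.

`site_accessibility()` classifies a site by its centre:

* **linker_slidable** — outside the core (reachable by sliding);
* **edge_slidable** — |SHL| ≥ 7 after half-integer rounding (the outermost
  reach of sliding on a nucleosome);
* **core_3d_exposed** — inside the core with its rotational phase facing the
  solvent, reachable only by direct 3D collision;
* **core_occluded** — histone-facing, inaccessible.

The solvent rule uses a plain 10-bp helical period: a core site is exposed
iff `((centre - dyad) + phase_offset) mod 10` falls in a half-period window,
`[3, 8)` by default. The only experimental constraint on this rule is that a
5-bp shift flips exposure (the SHL5 → SHL4.5 and SHL3 → SHL2.5 designs), and
any half-period window satisfies it; `[3, 8)` additionally makes the
standard constructs built by `template_601()` come out histone-facing at
SHL5/SHL3 and solvent-facing at SHL4.5/SHL2.5, as observed. We chose the
integer period 10 over 10.43 for testability; within a 147-bp core the
accumulated phase error is under half a base pair per turn and does not
change any classification used here.

Construct builders (`template_cognate_dna()`, `template_noncognate_dna()`,
`template_hsp70()`, `template_601()`) reproduce the experimental geometries
— lengths, motif placement, label assignment, linker arms, dyad — on
synthetic background sequence (seeded random DNA scrubbed of `GAGAG` on both
strands). Nucleosome positioning is declared by the dyad annotation rather
than encoded in sequence thermodynamics, which are out of scope.

## The stochastic search model

`simulate_path()` runs an exact continuous-time (Gillespie) simulation; all
sub-frame structure exists in the ground truth and frame-rate effects enter
only at rendering. The state is either *unbound* or *bound at base pair p*:

* **Association** at rate `k_assoc` (s⁻¹ per trace, proportional to protein
  concentration). Landing is uniform over slidable DNA (linker plus
  nucleosome edge); with probability `direct_3d_fraction` the landing goes
  directly to a solvent-exposed core site instead, when one exists.
* **Sliding**: nearest-neighbour hops at rate `D1` per direction
  (`D1` in bp² s⁻¹), the convention under which MSD = 2·`D1`·t. Hops into
  the occluded core are blocked when `occlusion_enabled`.
* **Motif trapping**: entering a site footprint traps the walker; the only
  exit is escape at the site's `k_escape`, to a base pair just outside the
  footprint. A trapped walker on a landlocked (solvent-exposed core) site is
  released into solution on escape.
* **Dissociation** from nonspecific positions at `k_off_ns`.

Defaults are the study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| `k_assoc` | 0.028 s⁻¹ | cognate-DNA binding frequency at 0.2 nM |
| `k_off_ns` | 3 s⁻¹ | 0.33-s nonspecific event dwell |
| `k_escape` | 4 s⁻¹ | 0.25-s microscopic motif dwell |
| `D1` | 160 bp² s⁻¹ | see below |
| `direct_3d_fraction` | 0.2 | order of the observed direct-binding fractions at exposed sites |
| `fret_radius` | 2 bp | FRET rendered as binary site proximity |

`D1` deserves comment. In this per-base-pair kinetic scheme the overall
dwell on a cognate fragment is set by the fraction of bound time spent in
dissociation-competent (nonspecific) positions. With `k_escape` = 4 s⁻¹ and
two sites on a ~190-bp fragment, `D1` ≈ 160 bp² s⁻¹ makes that fraction
about one tenth, i.e. an overall cognate dwell an order of magnitude longer
than the 0.33-s nonspecific dwell — the observed cognate/noncognate ratio.
A much larger `D1` would trap the walker at motifs essentially forever; a
much smaller one would never find them. Note that fast *apparent*
site-to-site transitions do not require a large `D1` here: transits compete
against dissociation, so the transits that complete are strongly biased
toward the fast tail of the first-passage distribution.

FRET is modeled as binary site proximity (within `fret_radius` of a labeled
site), not a continuous distance–efficiency curve: the experiments read
FRET as a site-occupancy indicator and dual-acceptor distances are not
calibrated. The per-event log also records landing position, whether the
landing was direct-3D, and the extreme positions visited, which is what the
occlusion tests interrogate.

The sliding kernel is implemented in C++ (Rcpp) because a single trace can
contain millions of hops; everything else is R.

## Rendering into traces and kymographs

`render_trace()` bins a path into camera frames under an excitation
schedule (`schedule_three_color()`: 10 frames Cy7, 10 Cy5, 960 Cy3, 10 Cy7,
10 Cy5; `schedule_two_color()`: 10 Cy5 then 990 Cy3). Each frame's channel
means are the *time-weighted mixture* of the emissions of the states visited
during that frame — so a dwell shorter than a frame produces a
proportionally dimmer signal, which is what makes sub-frame events hard to
detect. Gaussian noise and a constant background are added per channel.
Acceptor-excitation blocks report direct acceptor fluorescence only and are
used as fluorophore-presence checks; they are excluded from decoding (their
state labels are `NA`). Photobleaching draws one exponential time per
fluorophore; a bleached acceptor renders as donor-only.

`simulate_kymo()` renders reflected 1D Brownian motion on a tether as
repeated confocal line scans: a Gaussian point-spread profile (sd ≈ 1.3
pixels) with Poisson photon statistics, optional immobilization at target
positions, and optional multimer photobleaching (n independent fluorophores
giving stepwise-gradual intensity loss).

Every stochastic function takes an explicit seed and restores the caller's
RNG state; identical seeds give identical output.

## Binding-site assignment

`detect_events()` finds maximal runs of donor-excitation frames whose total
intensity exceeds `mean + k_sigma * sd` (default `k_sigma` = 3).

`fit_hmm()` is a Baum–Welch estimator with one state per labeled site plus
*unbound* and *nonspecific*, diagonal-Gaussian emissions over the three
channels, seeded k-means initialization, and a variance floor (a
zero-variance channel is regularized with a warning). Unbound ↔ site
transitions are allowed — direct 3D binding to a site is a real path.
States are labeled afterwards by emission signature (lowest total mean is
unbound; acceptor-dominant states are site states). The original analysis
this replaces used an HMM whose exact state space and emission family are
not public; this module is a defensible substitute and makes no claim of
equivalence. `viterbi_assign()` returns the MAP path; ties break toward the
lower-indexed state, making decoding deterministic.

`relative_intensity_assign()` implements the simple per-frame rule: within a
detected event, Cy5 stronger than Cy7 and above the FRET threshold
(`background + 3 sd` by default) assigns the Cy5 site; Cy7 stronger assigns
the Cy7 site; only Cy3 present assigns nonspecific. An exact above-threshold
tie carries the previous frame's label (nonspecific at the start of an
event). Both assignment routes are invariant under uniform intensity
scaling when thresholds are scaled identically.

`direct_transitions()` counts, within each binding event, successive
site-to-site visits; a transition is *direct* when no nonspecific frame
intervenes, the signature of a transit faster than one camera exposure.

## Dwell-time kinetics

`extract_dwells()` turns maximal state runs into dwell records (duration =
run length × frame interval), flagging runs that touch the trace boundaries
as censored. Censored dwells are excluded from survival fits by default —
mirroring manual start/end scoring — with a Kaplan–Meier-based inclusion
(`include_censored = TRUE`, via the survival package) as a sensitivity
check.

`fit_survival()` computes the empirical 1 − CDF at the sorted dwell times
and fits `y = y0 + A exp(-x/tau)` by nonlinear least squares
(`minpack.lm::nlsLM`), unweighted. The amplitude `A` is free: survival data
start near 1, and fixing `A = 1` would make `y0` absorb lack-of-fit. The
least-squares covariance understates the sampling error of `tau` because
neighbouring survival points are strongly correlated; with `n_boot > 0` the
`tau` standard error and CI come from a nonparametric bootstrap over dwells
instead, which is what the recovery tests use. A mixture of two dwell
populations yields an intermediate `tau` and a larger fit residual — the
residual is the flag, not a model-selection device (multi-exponential
models are out of scope).

`binding_frequency()` is events / (video length × trajectories);
`waiting_time()` reports its reciprocal to two significant figures (half-up),
which reproduces printed-style values such as 560 s and 36 s from 0.0018 and
0.028 s⁻¹. `kinetic_kd()` estimates `k_on` as the through-origin slope of
frequency versus concentration and returns `K_D = k_off / k_on`.

`categorize_event()` implements the three published classification schemes
as ordered predicates on an event's state-visit sequence (composition;
landing-site; nucleosomal-motif access). `rebinding_matrix()` estimates the
row-stochastic next-event site preference per molecule, never pairing events
across molecules. `donor_delay_fraction()` counts events whose first decoded
frame is nonspecific with a later site frame (delay threshold one frame).

The experimentally reported success rates, delay fractions and category
percentages depend on unreleased raw data; the package asserts only
direction and consistency properties about them on simulations.

## Kymograph tracking and diffusion

`track_kymo()` seeds detections at per-line local maxima above a photon
threshold, suppresses plateau/shoulder duplicates within the refinement
window, and refines each position as a background-subtracted intensity
centroid whose window is iteratively re-centred (three iterations). The
re-centring matters: a fixed window clipped at the brightest pixel shrinks
apparent displacements and biases MSD slopes low by several percent.
Linking is greedy nearest-neighbour per line with maximum jump equal to the
track width (default 0.5 μm); crossing tracks are split rather than swapped
(a documented limitation), and tracks shorter than 3 lines are discarded.

`msd()` is the standard time-averaged estimator with overlapping pairs
(non-overlapping available behind a flag), maximum lag 5 by default.
`estimate_D()` fits MSD = 2Dτ + b by OLS with a free intercept absorbing
localization error. Following the per-trace-then-average convention,
`diffusion_by_track()` estimates D per track and averages. The full
simulate → track → MSD → OLS chain carries a small negative bias (a few
percent: linking truncates the largest steps, tether ends reflect, residual
centroid shrinkage); the recovery tests bound it at 15% of the planted
D = 0.15 μm² s⁻¹.

`classify_mobility()` applies the strict `D < 0.01` μm² s⁻¹ nondiffusive
threshold. `compare_groups()` is the two-tailed unpaired Welch *t*-test.
`convert_dna_length()` converts μm ↔ bp only under an explicitly chosen
context — 3.3 kbp/μm for stretched tethers or 0.34 nm/bp contour length —
because no single conversion is consistent with all printed pairs of values
(in particular a D quoted in both μm²/s and bp²/s units cannot be matched by
either convention, and the helper does not attempt to).

## Facilitated-diffusion calculators

One-dimensional Brownian scaling with a single degree of freedom:
`sliding_length(D, t) = sqrt(2 D t)` and its inverse
`required_D(L, t) = L²/(2t)`. This prefactor reproduces both printed
anchors — 2.5 μm² s⁻¹ to cross 1 μm in 0.2 s, and ≈0.25 μm at
D = 0.149 μm² s⁻¹ (the computed value is 0.2441; the source rounds it to
0.25) — so no prefactor ambiguity remains. `false_3d_fraction()` composes
the sliding length with a uniform landing probability, `min(1, l/L)`.
`fold_ratio()` fixes the reporting conventions mechanically: nearest integer
half-up, or one significant figure (half-up) for "~N-fold" claims.

## Detection-limit convention

"Events shorter than the camera exposure go undetected" is a statement
about practice, not an absolute of time-weighted rendering: a 60-ms dwell
still lights up 60% of one frame and clears a 3σ threshold. The package's
operational version, used by the detection-limit tests, requires two
consecutive frames above the half-amplitude point, under which no single
sub-exposure dwell can produce a detection; the residual risk is two
sub-frame dwells falling in adjacent frames, which the planted-dwell test
avoids by construction and real analyses accept as rare.

## What the generator does not emulate

Continuous FRET-efficiency photophysics, triplet blinking and spectral
crosstalk; force-dependent sliding; protein–protein cooperativity beyond
single-multimer immobilization at targets; camera artifacts (EMCCD
multiplication noise, pixel nonuniformity); intra-line motion blur in
kymographs; and sequence-dependent sliding energetics. Passing tests
therefore demonstrate correctness of the analysis chain under the stated
kinetic model, not robustness to every artifact of real recordings.

## Problem sizes in the shipped tests

The suite runs the Viterbi-versus-enumeration battery at 500 random traces
(≤ 8 frames, ≤ 4 states); dwell-recovery fits at 2,000 dwells per planted τ
(0.11, 0.25, 3.1 s); the occlusion property over 10⁴ binding events on the
SHL5 nucleosome; and the kymograph chain over 100 tracked molecules of
150 lines each. These sizes were chosen to make stochastic assertions
well-powered at fixed seeds while keeping the default test run fast.
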