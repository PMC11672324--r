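---
title: "Methods: quantifying exo-endocytic dynamics in membrane wound repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying exo-endocytic dynamics in membrane wound repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundsight)
```

`woundsight` quantifies laser-ablation plasma-membrane repair experiments:
punctate exo- and endocytic events in time-lapse movies, their spatial
organization around the wound, dye-influx resealing kinetics, and two
biophysical computations (membrane hole energetics and tether-force
plateau extraction). This vignette documents the models, the parameters
that matter, the synthetic-data generator the tests rest on, and the
design choices made where the problem was genuinely open.

## Coordinate, time, and unit conventions

All geometry is in micrometers. Pixel centers sit at integer positions,
0-based, with x along columns and y along rows; physical coordinates are
`(index - 1) * pixel_size`. Frame `f` is acquired at
`(f - n_prewound_frames) * frame_interval` seconds, so the last pre-wound
frame is t = 0 and the first post-wound frame t = one frame interval.
"Post-wound windows" such as the exocytic (0, 10] s window are half-open
in time, not frame counts, because acquisition frame rates vary between
experiments. Hole energetics use SI units internally (N, N/m, J, m) and
convert to pN/nm/µm only at the interface.

## The synthetic-data generator

No raw imaging data accompany the experiments the package targets, so the
generator is a first-class, tested module that reproduces the statistical
structure the analysis assumes — not a fixture. Its defaults encode the
acquisition conditions of the emulated assays: 512 × 512 pixel frames, a
circular wound ROI of 2.5 µm² (20 pixels in diameter, which fixes the
default pixel size at √(2.5/π)/10 ≈ 0.0892 µm), two pre-wound frames
followed by 100 post-wound frames, and a ~30 s resealing phase.

Events form an inhomogeneous spatio-temporal Poisson process over an
elliptical cell footprint — the simplest generative model consistent with
independently appearing punctae:

* a stationary birth–death background on both marker channels
  (`steady_rate` events µm⁻² s⁻¹, exponential lifetimes with mean
  `lifetime_mean` = 4 s). Punctae already alive at acquisition start are
  included (with birth times before the first frame), so pre-wound frames
  carry the baseline counts the normalization needs;
* a wound-evoked exocytic burst during `exo_window` = (0, 10] s:
  the exocytic rate is multiplied by `exo_boost_by_ring[k]` inside
  concentric ring k (Poisson thinning against the maximum factor keeps the
  process exact). The ablated disk itself uses the ring-1 factor — the
  burst concentrates at the wound edge;
* a delayed endocytic burst after `reseal_time`: with probability
  `assoc_prob` an event is placed on a uniformly chosen earlier exocytic
  event plus isotropic Gaussian jitter (`assoc_sd`), otherwise uniformly
  in the cell. This directly encodes the "endocytosis at sites of prior
  exocytosis" structure the nearest-neighbor statistic must detect, and
  gives a closed-form calibration target: the fraction of endocytic
  events within 2·`assoc_sd` of their parent converges to
  `assoc_prob · (1 − e⁻²) ≈ 0.865 · assoc_prob`.

Rendering draws each live event as a Gaussian spot (`spot_sigma` =
0.15 µm, a diffraction-limited PSF at the default sampling;
`spot_amplitude` = 200 against `noise_sd` = 20 gives SNR 10 by default).
Channel 1 carries the wound dye: the cell outline plus low interior
signal, and after wounding either saturating influx
I₀(1 − e^(−t/τ)) (resealed) or linear influx (failed), plus a localized
Gaussian accumulation at the wound site. A second, dimmer unwounded cell
is rendered as the background/bleaching reference — its corrected
pre-wound intensity must stay below the wounded cell's for the influx
normalization to be defined. Bleaching is multiplicative
e^(−bleach·t) before noise; noise is Gaussian read noise with optional
Poisson shot noise. Identical configuration and seed give bit-identical
output.

Because the emulated association experiments co-express two markers, a
movie carries up to three channels (dye, exocytic marker, endocytic
marker); single-marker movies have two.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: pH-dependent reporter photophysics, cell
retraction and migration (such cells were excluded upstream in the
emulated workflow), 3-D structure, spatially correlated background, and
non-Poisson event clustering beyond the explicit exo→endo coupling.

## Punctae detection

The original workflow used an interactively trained pixel classifier,
which is not reproducible in code; the deterministic stand-in is
band-pass filtering (difference of Gaussians at `band_pass_sigma` and
3× that scale), thresholding, connected components, and an area filter
in µm². Probability-map ingestion (`binarize_probability_maps()`)
preserves the original route for users who have classifier output.

The default threshold is robust and scale-adaptive: `median + 6 · mad`
of the band-pass image. A blank frame therefore yields no detections, and
raising the threshold can only shrink the detection set (monotonicity).
A fixed-quantile kind is also available but always selects pixels, even
in event-free frames; the z-score default is why the detector holds
precision ≈ 1 on noise. The "strict" preset (10 robust SDs) mirrors the
higher-stringency setting used when compiling nearest-neighbor reference
events. Centroids are intensity-weighted over the band-pass excess;
sub-pixel Gaussian fitting is deliberately out of scope (the analysis
counts punctae, it does not track them). Size-filter bounds default to
[0.02, 3] µm², matched to the synthetic PSF, and are configuration, since
the emulated workflow does not state its bounds.

## Ring quantification

`build_rings()` surrounds the wound ROI (radius √(area/π) ≈ 0.892 µm)
with annuli whose outer diameters grow by 20 µm per ring: outer radius of
ring k = wound radius + k · increment/2. Whether the original circle ROIs
were annuli or nested disks is not stated; rings are **disjoint annuli by
default** (heatmap rows read as per-region densities), with
`cumulative = TRUE` providing the nested-disk reading. The wound disk is
excluded from ring 1 by default — ablation destroys signal there —
and annulus boundaries are half-open with boundary points belonging to
the inner region, so every centroid is assigned exactly once.

`count_matrix()` normalizes each ring's per-frame count by (i) the count
at the baseline frame — the last pre-wound frame — with zero baselines
clamped to 1 so normalization is defined everywhere (at the cost of
understating increases in rings that started empty), and (ii) the full
annulus area in µm². Mask-intersection areas are available as an option
but full annulus area is the default, matching the emulated
normalization. `steady_state_matrix()` is the area-only variant for
unwounded controls; algebraically it is the count matrix multiplied back
by `max(baseline, 1)`, and the tests assert exactly that identity.

## Resealing kinetics

The influx read-out is mean dye intensity over the wounded cell minus the
mean over a nearby unwounded cell (background and bleaching correction in
one subtraction — the direction is fixed as wounded − unwounded so that
influx increases the curve), normalized to the corrected value at the
last pre-wound frame. A non-positive reference refuses to normalize.

Plateau-versus-linear was a visual call in the emulated workflow; the
codified rule fits least-squares slopes on an early window (first third
of the post-wound record) and a late window (last third) and classifies
by the late/early slope ratio with threshold 0.2. All three knobs are
arguments. The early slope must be credibly positive (> 0 and > 2
standard errors) or the curve is *indeterminate* — a perfectly flat curve
carries no influx signal and should not be called either way. The rule is
invariant to adding a constant and to global intensity scaling, both of
which the tests check.

The hydrogel metrics are implemented as specified by their contracts:
mean dye intensity in a 20 µm wound-centered disk normalized to the
whole-cell pre-wound mean; delineation area as a fraction of cell area;
and the scrape-assay repair percentage
100·(n_wounded − n_failed)/n_wounded.

## Colocalization and nearest-neighbor association

Object-based colocalization counts a puncta of set A as colocalized if
its pixel mask overlaps any mask of B (or, under the centroid rule, if
the nearest B centroid is within a tolerance); each A-puncta counts at
most once, and the colocalized counts feed the same ring/baseline/area
normalization as the count matrix.

The nearest-neighbor series compiles reference positions from exocytic
punctae in a stated ring set during (0, 10] s post-wound, then for each
later frame averages the distance of every endocytic puncta to its
nearest reference position, normalizing the per-frame means to an early
post-wound frame. Choices that were open:

* the per-frame aggregate is the **arithmetic mean** (median available
  via `agg`);
* the normalization frame defaults to the **earliest post-wound frame
  with at least one endocytic puncta** — the literal first post-wound
  frame errors out when it happens to be empty under sparse steady
  processes, while an explicitly passed empty frame still refuses;
* frames with no endocytic punctae propagate as missing values, never
  zero — a zero would fake perfect association;
* nearest-neighbor ties resolve to the lowest reference index
  (deterministic, and irrelevant to the distance value).

The far-field control (`nn_control()`, circle 6 by default) repeats the
computation with references far from the wound; under coupling confined
to the wound zone it shows no post-resealing decrease. On ≤ 200-point
sets the vectorized search is checked against an exhaustive all-pairs
minimum, exactly.

## Hole energetics and tether forces

H(R) = 2E + 2πRλ − πR²σ with components H_line = E + 2πRλ and
H_tension = E − πR²σ. Since H is concave (d²H/dR² = −2πσ < 0), the
stationary point dH/dR = 0 at R_c = λ/σ is an energy **barrier**, and the
package documents and tests it as such: fate is decided by the sign of
dH/dR, equivalently R versus R_c, with a gradient-flow relaxation as the
test oracle. The additive energy E never enters fates or R_c. The model
reports the critical length λ/σ itself — 100 nm at λ = 1 pN,
σ = 10⁻⁵ N/m, and 1 µm after a tenfold tension reduction — and leaves the
radius-versus-diameter reading to the caller, since the emulated
discussion phrases the same quantity both ways. `tension_scan()`
evaluates fate under scaled σ; reducing tension can only convert growth
to resealing, never the reverse, and the scan asserts that monotonicity.

Tether traces (1000 samples/s) are reduced to (peak, plateau): baseline
and noise from the leading 10% of the trace; "no tether" if the maximum
does not clear baseline by 5 noise SDs; the peak is the global maximum;
the plateau onset is a change-point where the smoothed derivative
magnitude falls to 5% of its post-peak maximum **and** the smoothed force
agrees with a tail-of-trace plateau prior within 3 smoothed-noise SDs.
The value condition matters for shallow relaxations whose derivative is
buried in noise. The window then starts half the detected relaxation span
later again — a deliberate conservative guard so residual relaxation
cannot bias the plateau mean — and runs to the trace end. The smoothing
support is skipped after the peak so the rise-to-relaxation transition of
the smoothed derivative cannot masquerade as the plateau onset. On
noise-free traces the extraction is exact; on noisy traces the recovered
plateau is an unbiased mean of n detected samples and the tests hold it
to the 3σ/√n CLT bound.

The synthetic trace generator uses linear rise and linear relaxation
segments, with the relaxation reaching the plateau exactly at the segment
end and a plateau of at least half the trace — so the noise-free plateau
is exactly the ground truth and the CLT bound is the only error source.

## The pipeline

`run_pipeline()` executes simulate → detect → quantify → kinetics →
nnassoc from one nested configuration (YAML or list), writes CSV/JSON
artifacts, and records a manifest with the configuration hash, package
version, seed, and md5 checksum of every file. Identical configuration
and seed reproduce identical checksums; a failing stage writes a manifest
naming the failed stage and the completed artifacts before propagating
the error. Degenerate situations (e.g. an empty far-field reference set)
surface as explicit warnings, never silently.

## Problem sizes and numerical tolerances

The test and demonstration runs use reduced problem sizes chosen to
exercise every code path with comfortable statistical margins: event-only
calibrations on a 30 × 26 µm-semi-axis cell with rings of 8 µm diameter
increment (so circle 6 lies inside the footprint), rendered movies of
96–256 pixels square over 8–50 frames, 20-seed replications for
stochastic properties, 40 movies for resealing classification, and 50
random tether traces of 1200 samples. Statistical assertions use
3-sigma/Poisson/binomial bounds on pooled counts; exact assertions
(geometry, identities, determinism, oracle equalities) use tolerances at
or near machine precision — the closed-form/numeric stationary-point
agreement is held to a relative 10⁻¹⁰ over a four-decade parameter grid.

## Known limitations

The detector performs no sub-pixel localization or temporal linking;
overlapping punctae within ~2 PSF widths merge (the dominant recall loss
at high densities). Ring areas default to full annuli even where the
annulus leaves the cell footprint, exactly because that is the emulated
normalization — per-cell masking is available but changes the scale of
the values. The classification rule reduces a visual judgement to two
slopes and one ratio; curves that plateau late relative to the recording
window can read as failed. The hole-energetics model contains no bending
energy or pressure coupling, and tether force is reported as a relative
tension indicator, not converted to absolute tension (that would require
the bending rigidity). Statistical comparison across cells (ANOVA and
rank tests on these outputs) is deliberately left to standard tools.
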