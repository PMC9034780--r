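---
title: "Mapping dendritic input domains with sCRACM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dendritic input domains with sCRACM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scracm)
```

## The measurement problem

Subcellular channelrhodopsin-assisted circuit mapping (sCRACM) asks *where
on a neuron's dendritic tree* a given long-range pathway makes functional
synapses. Axons from one input area express an opsin; a brain slice is
bathed in TTX and 4-AP so that only directly illuminated terminals
release; and a grid of brief light spots is scanned over the recorded
cell while EPSCs are collected in somatic voltage clamp at -70 mV. The
charge (time-integral) of the evoked current at each spot, rather than
its peak, is used because charge is less distorted by dendritic
filtering. Accumulated over a 24 x 12 grid of 41.7 um spots spanning
1000 x 500 um (spot irradiance 173 mW/mm^2 at 300 uW per spot), the
per-spot charges form a 2D input map for one cell.

This package implements the full analysis from raw sweeps to per-area
summaries, together with a synthetic-data generator so that every stage
can be validated against a known ground truth. The per-cell estimator is
`fit_scracm()`, which returns a classed object with `print()`,
`summary()`, `coef()` and `plot()` methods; the quantity it estimates is
the cell's input map and its allocation among the three dendritic
compartments of a thick-tufted layer 5 (ttL5) pyramidal neuron — basal
dendrites (originating at the soma), oblique dendrites (branching from
the apical trunk below the main bifurcation, including the trunk
itself), and the apical tuft (distal to the bifurcation).

## Trace analysis

Each spot's trace is baselined on the 40 ms before its stimulus and
averaged across trials; peak and charge are measured in the 50 ms after
the stimulus (trapezoidal quadrature on the raw 20 kHz samples; no
further filtering). A response is included if its peak exceeds **7x the
baseline SD of the trial-averaged trace** — the threshold is applied to
the average, not per trial, which matches thresholding the quantity that
enters the map. Non-significant spots contribute zero charge to the map.
Inward currents are reported as positive charge throughout.

Two QC rules are applied per cell: recordings with series resistance
*strictly above* 40 MOhm are discarded, and cells showing
direct photocurrent (from retrograde opsin expression in the recorded
cell) are excluded. The direct-photocurrent criterion is an onset bound:
synaptic responses have a few milliseconds of synaptic delay, while
direct photocurrents begin almost immediately, so any significant spot
whose onset latency falls below 2 ms flags the cell. Onset is measured
as the 3x-SD crossing *attached to the measured peak* (the start of the
contiguous supra-threshold run containing the peak) rather than the
first crossing anywhere in the window; with a 7x-SD peak criterion a
first-crossing rule would be tripped by isolated noise excursions at a
rate of several spots per cell, whereas the attached-crossing rule is
noise-robust and identical on clean traces. Both the 2 ms bound and the
3x multiplier are configurable in `analysis_config()`.

A detection-bias audit (`detection_bias_check()`) correlates each cell's
peak-input depth with its full-field charge: distance-dependent
attenuation would make weak cells look proximally biased; an absent
correlation argues against such bias.

## Maps, alignment, and the 20.83 um lattice

Somata are localized to one quadrant of a stimulation spot, so all maps
are worked at quadrant resolution: native spots are upsampled 2x with
each spot's charge split equally over its four quadrants (conserving
total charge), giving 20.83 um pixels (1000/48 um exactly). Maps are
peak-normalized per cell, aligned horizontally on the soma column and
vertically on either the pia or the soma, and averaged over the union
canvas with per-pixel divisors equal to the number of contributing cells
(edge pixels average over the cells that actually reach them).
Projections onto the depth or mediolateral axis are sums, not means, so
they conserve charge exactly; peak locations and horizontal biases are
therefore integer multiples of 1000/48 um before being rounded half-up
to integer micrometres — reproducing the published 21/42/63/83/104 um
lattice. Ties between equal maxima break toward the anchor. Tuft
measurements are reported as depth from the pia; basal and oblique
measurements as signed distance from the soma (positive toward the
pia); horizontal bias is positive medial.

Matrix convention: rows index cortical depth (row 1 at the pia), columns
the mediolateral axis, with `medial_sign = +1` meaning increasing column
index points medially. The grid's long (1000 um) axis runs along the
cortical depth, covering the full cortex, as in the recordings.

## Morphology profiles and compartment allocation

Reconstructed morphologies are reduced to depth profiles: dendritic
length per 10 um bin along the apical axis, per compartment, with each
segment's length apportioned to bins by linear overlap of its depth
span. Compartment labels are derived from topology: the main
bifurcation is found by walking the apical trunk from its root along the
heaviest daughter until a second daughter subtree first holds at least
25% of the remaining apical length (the threshold is configurable; real
ttL5 bifurcations are visually obvious and far above it). An apical tree
that never satisfies the rule is labeled all-oblique with a warning.

Profiles from several cells are averaged after linearly rescaling depth
so that each cell's soma-pia distance maps to a common target; because
the rescaling anchors the pia at 0 *and* the soma at the target depth,
pia-aligned and soma-aligned averaging coincide, and a single
depth-from-pia grid serves all downstream uses (the reported axis
convention is still selectable). Rescaling conserves per-compartment
total length (re-binning by overlap), within 0.5%.

Allocation ("deconvolution with the average morphology") is bin-wise
length-share weighting, not a sliding convolution: in each 20.83 um
depth bin the measured charge is split among compartments in proportion
to their share of dendritic length there. This is the only reading of
the procedure that produces compartment proportions, and it makes
allocation scale-invariant in the input and exactly charge-conserving.
Length is an adequate proxy for synaptic opportunity because spine
densities are similar across the three compartments. Bins that carry
charge where the (rescaled) morphology has no dendrite — possible at
map edges after alignment — borrow the shares of the nearest bin with
dendrite, so no measured charge is silently dropped (a `drop` mode is
available). Proportions times the full-field total give absolute
compartment charges; `aggregate_splits()` pools areas by summing
charges and dividing by the grand total.

## Peters'-rule predictions

Peters' rule posits synapse counts proportional to axo-dendritic
overlap. `predict_input()` resamples a laminar axon-density profile and
the pia-aligned total dendritic-length profile onto a common 20.83 um
grid, peak-normalizes each factor, and multiplies bin-wise; the result
is invariant to positive rescaling of either factor. Because the
original study overlays predicted and measured curves without a
statistic, the package reports cosine similarity (primary; it ignores
overall scale and is defined for non-negative profiles) and Pearson
correlation (secondary), plus the per-bin difference profile.

## The synthetic generator and what it does (not) show

The generator exists so every stage is testable without raw recordings;
its defaults are fixed study conditions, not tuning knobs.

* **Protocol constants** follow the published design: 24 x 12 spots,
  1 ms stimuli at 10 Hz in a pseudo-random order, one full repetition of
  all 288 spots plus a full-field stimulus per trial, 20 kHz sampling at
  -70 mV. The pseudo-random order is drawn by rejection: permutations
  are redrawn until no two consecutive spots are 8-neighbors on the
  grid (the published optimizer is unspecified beyond maximizing
  consecutive-spot distance; the adjacency property is what the analysis
  relies on, since it keeps successive responses from overlapping in
  space). Acceptance probability is ~6e-4, so a few thousand cheap draws
  suffice; a deterministic swap-repair backstop exists.
* **EPSC kernel**: difference of exponentials with 2 ms rise and 15 ms
  decay, preceded by a 3 ms synaptic latency. The sampled kernel is
  windowed to the remainder of the 50 ms response window and normalized
  so its trapezoidal integral is exactly 1; a scaled copy therefore
  deposits exactly the requested charge as seen by the analysis
  quadrature (the un-windowed kernel would leave ~4% of its mass outside
  the window; windowing trades a ~0.3%-of-peak truncation step for exact
  conservation). The latency separates synaptic onsets (>= 3 ms) from
  the simulated direct-photocurrent case used in tests.
* **Per-spot charge model**: charge proportional to (dendritic length of
  each compartment under the spot) x (compartment targeting weight),
  scaled so all spots sum to the session total; per-compartment sums
  then equal the targeting split exactly, and the full-field charge
  equals the sum of all spots. This is the simplest model consistent
  with uniform spine density; it ignores release stochasticity and
  full-field desensitization.
* **Morphologies** are stylized 2D ttL5 trees: radiating basals around
  and below the soma, a trunk ascending to a bifurcation at ~45% of the
  soma depth, obliques with mild upward tilt confined below the
  bifurcation, and a balanced tuft reaching the pia. Compartment depth
  bands are constructed to order tuft < oblique < basal from the pia, as
  in real reconstructions; band separation is what limits the intrinsic
  bias of length-share allocation (compartments overlapping in depth
  cannot be distinguished by any depth-profile method).
* **Noise** is white Gaussian, 0.5 pA SD per raw sample, with 10 trials
  and a 10 pC session total by default. The sub-pA scale is what the
  published protocol implies: full-field totals near 1 pC spread over
  288 spots mean per-spot charges of a few fC, detectable at 7x SD only
  if the averaged-trace noise is well below a picoampere. Soma depth
  defaults to 500 um (area means span 435-521 um), and the default
  targeting (0.25/0.50/0.25) mirrors the observed cross-area aggregate
  allocation (27/49/24%). Trials within the published 5-20 range.

What passing tests show: the estimator recovers known compartment
targeting to ~1 percentage point at these conditions, the 7x-SD rule
admits essentially no false positives on pure noise, and charge is
conserved bit-exactly through map building, projection and allocation.
What they do not show: robustness to 1/f and synaptic background noise,
release stochasticity, slice-angle artifacts, light scattering (true
optical resolution ~60 um), or voltage-clamp escape — none of which the
generator emulates.

## Numerical and design choices

* Trapezoidal integration on raw samples; charges in pC (1 pC = 1000
  pA*ms).
* Baseline SD on the trial-averaged trace; a pooled per-trial SD
  (divided by sqrt(trials)) would be an alternative with slightly
  different small-sample behavior.
* Rounding of reported distances: half away from zero, matching the
  published 63 = round(62.5) pattern.
* Averaged maps track per-pixel cell counts; profiles of averaged maps
  are computed after averaging (average-then-project). Projecting first
  and averaging profiles gives the same result up to edge-canvas
  weighting; the map-first order is the default because the published
  average heatmaps are themselves averaged maps.
* "Peak in tuft" per cell compares the argmax depth of the cell's
  vertical profile with the cell's rescaled main-bifurcation depth.
* SEM uses the n-1 standard deviation and is reported as `NA` for
  single-cell areas.
* Problem sizes in the shipped tests: cohorts of 10 simulated cells,
  10-seed property checks, and 2-3-trial reduced-rate sessions where
  numerical precision is not at stake; these sizes make the full suite
  run in about a minute while leaving every statistical check
  well-powered.

## Known limitations

Depth-profile allocation cannot separate compartments that overlap in
depth — charge in shared bins is split by length share, which biases
strongly asymmetric targeting toward the length-dominant compartment;
with realistic band separation the residual bias is ~1-2 percentage
points. The morphology average assumes stereotypical trees (justified
for ttL5 cells). Rabies-count comparisons treat counts as given; no
correction for tracing efficiency is attempted. The session reader
expects the package's documented directory layout rather than a binary
container format.
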