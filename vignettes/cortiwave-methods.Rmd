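---
title: "Methods: wave propagation and network states on micro-ECoG grids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wave propagation and network states on micro-ECoG grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortiwave)
```

# The data model

Everything runs on an `mc_recording`: a `channels × samples` matrix of
field potentials in microvolts, a sampling rate (10 kHz per channel on the
target hardware; any rate above twice the band of interest works), and a
`grid_geometry` describing the electrode lattice — by default 8 × 8 at
500 µm pitch. Channels are indexed 1 to 64, row-major from the top-left
corner of the array as drawn; this is the R convention and every map, map
export and direction label uses it. The array frame is not anatomical:
nothing in a recording says which way the grid sat on the cortex, so
"right-to-left" always means *across the array as indexed*, not across
the brain.

Channels with unusable electrodes (e.g. high impedance) are declared in
`bad_channels` and **excluded from every downstream statistic** — delay
features, connectivity, synchrony — rather than interpolated. Exclusion
never fabricates data; grid maps simply show those cells as missing.

Recordings are stored in a plain-text CSV container (`save_recording` /
`load_recording`): two comment lines carry the sampling rate and the full
geometry as JSON, then one row per channel. Values are printed with 17
significant digits, so a round trip is bit-exact. Loading validates the
channel count against the declared geometry and rejects non-finite
samples, naming the offending channel and sample.

# The synthetic generator

The generator exists so that every analysis stage can be verified against
known ground truth. It is deliberately phenomenological — no neural-mass
or cable biophysics — and emulates exactly the statistical structure the
analyses assume:

* **Stationary oscillations** (`gen_stationary`): every channel carries
  `A·cos(2πft + φ₀)` with a common `φ₀`; defaults f = 7 Hz, A = 50 µV
  (a low-amplitude anesthesia-band rhythm). This is the regime in which
  phase maps are flat, the synchrony index is 1, and delay matrices
  vanish.
* **Plane-wave spike events** (`gen_plane_wave_event`): the channel at
  position **p** (µm) receives a spike template delayed by
  `(p·û)/v` ms for unit direction `û` and speed `v`. The default speed,
  50 µm/ms, makes the wave cross the 3.5 mm array in 70 ms — the
  tens-of-milliseconds scale seen in vivo. The returned `true_delays`
  field is exactly that inner product, the ground truth for every delay
  test.
* **Spiral events** (`gen_spiral_wave_event`): a pure rotating-phase
  field — arrival offset `±θ/ω` for polar angle θ about the centre, sign
  by chirality. Arrival time depends on angle only, so the field winds by
  exactly one full turn (`2π/ω` ms, default ω = 0.1 rad/ms ≈ 63 ms per
  turn) around the centre. This is the minimal model that produces the
  angular-wrap delay-map signature of a rotating wave; real spirals also
  have radial structure, which this model intentionally omits.
* **The spike template** (`spike_waveform`): a 40 ms biphasic wave — a
  half-sine depolarisation over the first 45% of the duration followed by
  a 30%-amplitude opposite-polarity rebound — with mV-scale amplitude
  (default 3000 µV). In vivo spike shapes vary; the template is evaluated
  in continuous time so fractional-sample delays are exact, and both its
  duration and amplitude are configurable.
* **Background**: per-channel white noise plus a *common-mode surrogate* —
  a band-limited (default 1–10 Hz) random process added identically to
  every channel, standing in for volume conduction. Because it is exactly
  common, `subtract_common_mode` annihilates it, and the high-gamma
  filter removes it independently — each defence is verifiable on its
  own.
* **Planted connectivity** (`gen_seizure`): during each scheduled event,
  channels receive additional 80–120 Hz noise whose cross-channel
  correlation follows a block partition chosen *per event label*, so
  functional network states co-vary with propagation types by
  construction, with a tunable contrast (`hg_amplitude`, `hg_rho`).

All draws flow from one integer seed through fixed substreams
(background / events / high-gamma), so generation is bit-reproducible and
components can be regenerated independently. What the generator does
**not** emulate: electrode drift and impedance noise, non-stationary
oscillation frequency, spike-shape variability, finite wavefront width,
or any causal link between the low-frequency wave and the high-gamma
drive. Passing tests therefore demonstrate that the *algorithms* recover
planted structure under realistic geometry and noise — not that real
cortex contains such structure.

# Preprocessing

Three Butterworth presets mirror the standard bands: `theta` (band-pass
5–9 Hz, order 4), `epileptic_lowpass` (120 Hz, order 6) and `high_gamma`
(band-pass 80–120 Hz, order 4; the order of the high-gamma filter is a
package choice). All filters are applied **forward–backward**
(`signal::filtfilt`), i.e. zero-phase: delay estimation downstream must
not inherit filter group delay, and the suite checks that a filtered tone
has exactly zero lag against its input. The effective attenuation order
therefore doubles; presets are named by their design order.

The analytic signal is computed in the frequency domain (negative
frequencies zeroed, positive doubled) on the full segment, with no
padding. Instead of padding heuristics, the first and last 5% of samples
— or one period of the band's lower edge, whichever is larger — are
flagged unreliable, and events are windowed with margins so edges never
enter statistics. A constant channel has undefined phase and is flagged
rather than fatal. The synchrony index at sample t is the circular
resultant length `R = |mean over good channels of exp(iφ)|`: 1 for
perfect locking, 0 for uniformly spread phases.

# Spike-event extraction

Detection thresholds the **across-channel maximum absolute voltage** over
good channels (default 500 µV on the 120 Hz low-passed signal), so a wave
entering at any edge of the array is caught at its first strong channel;
a positive-polarity-only variant is available. Each supra-threshold
excursion seeds a candidate at its global peak; candidates closer than
the refractory interval (default 50 ms) merge into the larger-peak one.

Windows are 100 ms for ictal and 500 ms for inter-ictal spikes — sized so
each window holds exactly one spike complex. Which regime applies is
decided per event from a sliding 10 s local-rate estimate (ictal at
≥ 1 spike/s by default): a reproducible, configurable surrogate for
manual seizure-stage labelling, recorded per event. Windows are centred
on the peak (alignment is a package choice), clamped inside the
recording, and overlapping windows merge into the larger-peak event.

# Delay estimation

For one channel pair, the normalised cross-correlation is evaluated at
every integer-sample lag in `[−L, L]`: at lag τ the overlapping segments
are correlated with per-overlap mean and variance normalisation, so
amplitude differences between channels cannot bias the lag choice
(the cross term for all lags comes from one FFT product, the overlap
moments from prefix sums; the result is identical to the naive scan and
is property-tested against it). The reported delay is the maximising lag;
**ties break toward the smallest |lag|, then toward the negative lag** —
a deterministic rule that also resolves the periodic-signal case (a pure
tone correlates perfectly at every whole-period shift; the rule picks 0).
Degenerate overlaps (zero variance at some lag) are excluded from the
maximisation; a channel that is constant over the whole window is an
error. Sub-sample (parabolic) peak refinement is off by default — delay
maps are integer-sample quantities in ms — and available as a flag.

The default lag bound is half the event window (50 ms ictal / 250 ms
inter-ictal). Note that for synthetic events windowed tightly around the
crossing this can clip the extreme corner-to-corner delays; the bundled
event-set generators use 200 ms windows so the 70 ms crossing fits.

`delay_matrix` computes each unordered pair once and mirrors it, making
antisymmetry exact by construction. `peak_time_delay` is the simpler
cross-check estimator (per-channel global-peak times); on clean low-passed
events the two agree within a couple of samples. `delay_features` takes
only the delays against one reference channel — the first column of the
full matrix restricted to good channels. The full 64 × 64 matrix is
antisymmetric and hence redundant; one column (63 numbers) already
separates propagation types and avoids clustering a 4096-dimensional
vector.

# Wave classification

Plane-wave delay fields are affine functions of the electrode coordinates,
so the collection of such fields spans at most three dimensions (two
gradient components plus the reference offset); spirals add an angular
wrap. This geometry is why PCA on delay features concentrates essentially
all variance in the first three components, and why the pipeline projects
to three dimensions before clustering. PCA is mean-centred
(`stats::prcomp`), with component signs fixed so each component's
largest-magnitude coefficient is positive — component maps are then
reproducible across runs.

k-means is seed-dependent by nature, so `kmeans_cluster` runs `n_init`
(default 50) k-means++ seedings through `stats::kmeans` (Lloyd) and keeps
the lowest within-cluster sum of squares, under an explicit seed that
leaves the caller's RNG untouched. The elbow curve `W_k` is computed
best-of-`n_init` per k, with `W_1` the total sum of squares; the suggested
k maximises the second difference `W_{k−1} − 2W_k + W_{k+1}` (maximum
curvature). Human elbow-picking cannot be coded as stated, so the
suggestion is automated but reported *with* the raw curve, and flagged
low-confidence when the maximum curvature is under twice the median — a
single Gaussian cloud has no elbow and says so.

Clusters get semantic names from their centroid delay maps: a plane fit
over good channels with R² ≥ 0.8 yields the gradient's cardinal direction
(the delay gradient points along the propagation direction, since
downstream channels arrive later); otherwise a unit winding number of the
map around the channel centroid — delays rescaled to phases over their
span, wrapped increments summed along the angular ordering — yields
`spiral`; otherwise `other` (an all-zero map has neither gradient nor
winding). The 0.8 threshold separates the two regimes cleanly in
practice: an ideal plane fits with R² ≈ 1 even after integer-sample
quantisation, while a pure angular field fits a plane poorly on a
centred 8 × 8 lattice.

# Network states

Connectivity is *power-based*: per channel the high-gamma amplitude
envelope (analytic-signal magnitude) is extracted after common-mode
subtraction, and `C_ij` is the maximum over signed lags (default ±20 ms)
of the normalised cross-correlation of the two envelopes. Maximising over
signed lags makes the measure symmetric and delay-robust — a connectivity
measure penalising time delays would systematically differ between
propagation types and bias the comparison that is the whole point. The
normalisation makes it invariant to per-channel gain. A raw-signal
(non-envelope) variant is exposed for sensitivity analysis. Zero-variance
channels are excluded with a warning.

Event pairs are compared by Pearson correlation of the **strict upper
triangles** of their connection matrices: the matrices are symmetric with
unit diagonal, so full vectorisation would double-count every pair and
add 64 constant diagonal entries, inflating similarities.

Community detection maximises weighted Newman–Girvan modularity on the
similarity graph. Negative similarities are clipped to zero first
(classic modularity is defined for non-negative weights; the clip count
is recorded; signed modularity is out of scope), and the diagonal is
dropped. The search runs `n_init` (default 20) seeded restarts of
`igraph::cluster_louvain` under random vertex permutations, each polished
to a local optimum under greedy single-node moves and pairwise community
merges, keeping the highest-Q partition; the all-in-one partition (Q = 0
exactly) is the floor. On small graphs this reaches the
exhaustive-enumeration optimum (property-tested); on large graphs it is
the usual greedy heuristic. The resolution parameter defaults to 1.

# Association statistics

The state-by-type contingency table is tested with Pearson's chi-squared
(no continuity correction — that applies to 2 × 2 tables; these are
3 × 3, df = 4). Zero rows or columns are dropped with a warning before
the test; expected counts under 5 warn but do not error. Effect size is
Cramér's `V = sqrt(χ²/(n·(min(r,c)−1)))`.

Because the type labels come from seed-dependent k-means,
`repeated_association` re-clusters per run (seed `base_seed + r`, one
seeding per run by default — the run-to-run spread *is* the quantity of
interest) and tests against the fixed network states. The chance model is
a **label-permutation null**: per run the states are randomly permuted
(seeded), preserving both marginals — the standard chance model for
association at fixed marginals; a fully random-states alternative is a
one-line change. Real and null V samples are compared with a one-sided
Wilcoxon rank-sum test. Under independence the per-run permutation
p-values are iid uniform, which is also how the suite checks type-I
calibration: with states drawn independently of the features, the
fraction of permutation p-values below 0.05 stays inside binomial bounds
of 0.05. (The *re-clustering* p-values cannot serve that purpose: with a
fixed dataset, stable clusterings make them nearly identical across
runs.) The default is 1000 runs; the distributional conclusions are
runs-robust, and the run count scales up directly when an
exhaustive-style pass is wanted.

# Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: 300
synthetic spike events (100 per type, white noise sd 300 µV against
3000 µV templates) for classification recovery; 45 noiseless events for
the explained-variance geometry; 200 random signal pairs for the
delay-oracle equivalence; 100 random graphs of 4–8 nodes (exhaustively
enumerable: at most 4140 partitions) for the modularity optimum; 60
events for planted-state recovery; 1000 repeated association runs.
Tolerances follow the quantity: exact integer identities (df, lags,
winding) are compared exactly; unit-bounded statistics to 1e−12 where
algebra guarantees them; recovery scores as the inequalities stated above.

# Limitations

* Delay maps are the propagation representation; there is no optical-flow
  or phase-gradient velocity estimation, and no sub-sample delay
  refinement by default.
* Direction labels are array-frame, not anatomical.
* Connectivity is undirected; no Granger/transfer-entropy causality, no
  source localisation.
* The generator's spiral is angle-only; real rotating waves have radial
  phase structure the delay-map winding test does not need but real data
  may show.
* Modularity on clipped weights discards negative-similarity information.
* The CSV container is the only file format; it favours portability and
  inspectability over compactness (a binary container would be an easy
  extension).
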