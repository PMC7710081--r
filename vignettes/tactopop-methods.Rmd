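---
title: "tactopop: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tactopop: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by `tactopop`, the
assumptions baked into it, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made. It states no
empirical result that the test suite does not itself compute.

## 1. The single-neuron model

An FA-1 first-order tactile neuron is modelled as a set of mechanoreceptor
(MR) locations in a flat skin patch (coordinates in mm, origin at the
lower-left patch corner, stimulus motion along +x). The drive of one MR at
distance $d$ (mm) from the stimulus, with local indentation amplitude
$A$ (mm), is

$$ I_{MR}(d) = A\, w_{MR}\left(1 - \frac{1}{1 + e^{-5(d/r_1 - 1)}}\right),
   \qquad d \le r_1 + r_2, $$

and zero beyond the reach $r_1 + r_2$. Here $r_1$ (mm) is the sigmoidal
half-height distance, $r_2$ (mm) the additional reach, and $w_{MR}$
(Hz per mm of indentation) is shared by all MRs of a neuron and fixed at
twice the neuron's maximal firing rate, so that a 0.5 mm edge crossing an
MR can just sustain the maximal rate. Skin mechanics enters only implicitly
through this responsivity profile; there is no continuum-mechanical model
and no fingertip curvature.

**Spike initiation.** Each MR feeds a dedicated axonal branch with its own
spike-initiation zone, modelled as a phase accumulator: the phase integrates
$\min(I_{MR}, \text{max\_rate}) \cdot \Delta t$ (with gain 1 and
$\Delta t = 1$ ms) and the zone may emit a spike when the phase reaches 1.
Two gates apply:

* **adaptation** — a zone fires only while its drive is strictly
  increasing ($I(t) > I(t-\Delta t)$; equality counts as "remained the
  same" and blocks firing), and
* **threshold** — the *effective indentation* (the drive without
  $w_{MR}$, i.e. amplitude × sigmoid term) must be at least 0.01 mm.

While blocked, the phase is held at a ceiling of 1.

**Onset priming.** At rest the phase starts at 1 ("time from the last spike
is infinite"), so the first increasing supra-threshold input triggers an
immediate onset spike. This choice is forced by the windowed-presentation
experiments: during a 5 ms window the accumulator can gain at most
$\text{max\_rate} \times 5\,\text{ms} < 1$ of phase, so a zero-initialised
model would be structurally silent at short windows, contradicting the
fact that short-window discrimination works well above chance. It also
matches the physiology of fast-adapting afferents, which fire at
indentation onset.

**Reset scheme.** When a zone fires, the spike propagates retrogradely and
*resets the other zones' initiation* (their phases go to 0); the spiking
zone keeps its own post-spike phase remainder. This makes a one-MR neuron
behave identically under the reset, mixing (union of branch trains), and
summation (single accumulator on the summed drive) schemes, which is the
natural degeneracy requirement. Mixing and summation are implemented as
diagnostic variants only; reset is the default everywhere. At most one
neuron spike is emitted per 1 ms tick; simultaneous branch crossings are
resolved in favour of the lowest MR index, which is output-invariant.

## 2. Stimuli, noise, and presentation windows

The edge is an infinite zero-width line with signed orientation $\theta$
relative to the y axis (positive counterclockwise; $\theta = 0$ is
perpendicular to the motion direction), translating along +x at 30 mm/s
with amplitude 0.5 mm; $d$ in the drive equation is perpendicular
point-to-line distance. An *unlimited* presentation sweeps the line from
2 mm beyond one patch border to 2 mm beyond the other (the margin exceeds
the maximal responsivity reach of 2 mm); a *windowed* presentation of
$T$ ms covers $30\,\text{mm/s} \times T$ of travel centred on the patch.

Additive stimulus noise tiles the patch with fixed 0.4 × 0.4 mm squares
anchored at the origin; each tile carries one i.i.d. uniform amplitude
offset in $\pm \text{level}/100 \times 0.5$ mm, redrawn per trial. The
distribution is uniform — the minimal reading of "random amplitudes
ranging between" two bounds. Noise enters as a modulation of the amplitude
experienced at each MR location (floored at 0); it does not create
stimulus where the edge is absent. MRs of border neurons lying outside the
patch experience the unperturbed amplitude.

## 3. Fitting and model selection

The fitness of a candidate neuron against a recording is the coefficient
of determination between Gaussian-smoothed rate curves,
$R^2 = 1 - \langle (SR_m - SR_o)^2 \rangle / \langle (SR_o -
\overline{SR_o})^2 \rangle$, averaged over the four training orientations
(±22.5°, ±45°). The printed source formula is the raw residual/total
ratio; since good fits are reported near 1, the package returns
$1 - \text{ratio}$ and attaches the raw ratio as an attribute. The
rate-curve estimator is unspecified in the source; we use a unit-area
Gaussian kernel with $\sigma = 5$ ms on the 1 ms grid (a configuration
knob surfaced in `fit_dataset()`; all fitting results carry it). The
fitting target is the trial-mean rate curve per orientation, which reduces
jitter noise without changing the noiseless case.

The genetic algorithm optimises the MR locations (constrained to the
receptive-field region mapped by a moving-dot scan) plus $r_1 \in
[0.05, 1]$ and $r_2 \in [0.2, 1]$ mm. Published GA constants: population
100, mutation probability 0.1, crossover probability 0.1, 500 iterations
(200 for classifiers). Unpublished internals, chosen here and configurable:
tournament selection of size 3, elitism of 1, Gaussian location mutation
(sd 0.3 mm; proposals outside the region are retried and otherwise kept),
uniform crossover over MR slots. Model selection filters candidates fitted
with different MR counts: within 5 % (multiplicative) of the per-orientation
maximal training $R^2$ on all four orientations, then within 5 % of the
maximal cross-validation $R^2$, then within 5 MRs (additive) of the minimal
count; the survivor with the best cross-validation accuracy wins. A filter
that empties the candidate set is skipped with a warning rather than
failing.

Null models redraw the MR locations uniformly inside the RF region,
keeping everything else; the nearest-edge baseline scores the 22.5°
trial-mean curve against the 30° one (both truncated to the shorter time
grid, since sweep durations differ slightly with orientation).

**Dot-scan boundary.** The admissible MR region is mapped by sweeping a
dot stimulus along scan rows 0.2 mm apart and marking the dot position at
every evoked spike. The resulting point set is rasterised (0.1 mm cells,
dilated by the scan spacing) for membership tests and rejection sampling.
Note the boundary is a *spiking* boundary: it is slightly smaller than the
$r_1 + r_2$ reach because sub-threshold drive near the rim cannot
accumulate a spike during a passage.

## 4. Population and readout

The fingertip population tiles a 12 × 12 mm patch at 140 neurons/cm² with
uniformly rotated copies of the base neurons (rotation about the MR
centroid). Since the published population count (330) exceeds patch area ×
density (~202), centres are sampled over the patch dilated by the maximal
RF footprint radius and any instance with at least one MR inside the patch
is retained; `target_count` forces an exact size by drawing more
candidates.

Readout convolves each neuron's spike train with
$k(t) = e^{-t/\tau_d} - e^{-t/\tau_r}$ ($\tau_r = 0.5$ ms; $\tau_d = 3$ ms
AMPA-like or 65 ms NMDA-like), truncated at $8 \tau_d$ (tail mass
$< e^{-8}$) and normalised to unit peak so the two channels carry
comparable weight scales (raw mode is retained for sensitivity checks).
Each of two units (tuned to $-\theta$ / $+\theta$) takes a signed weighted
sum of the traces, one weight per (neuron, channel) in $[-1, 1]$ — negative
weights standing in for feed-forward inhibition with matching kinetics —
and the unit with the larger maximum of its *summed* trace decides the
trial; exact ties are resolved at random (and scored one half in batch
evaluations, which keeps them deterministic). Short presentation windows
append a 50 ms silent tail to the feature traces so PSPs can evolve past
the stimulus.

Classifier training maximises training success with the same GA constants
(200 iterations); fitness ties at 100 % training success are broken by a
bounded classification-margin bonus ($10^{-3} \cdot m/(1+|m|)$), which can
never outweigh a one-trial success difference but gives the GA a gradient.

**Simple receptive fields.** The single-MR comparison model
(`make_simple_rf_neuron()`) uses a half-height distance of 1.45 mm and a
reach of 1.5 mm: a smooth, symmetric responsivity profile the size of an
average recorded receptive field. The opposite assignment (half-height at
0.05 mm) would collapse the sigmoid — whose slope scales with the inverse
half-height — into a ~0.1 mm point detector; an array of such detectors
reports edge-crossing times with near-perfect precision and *outperforms*
complex receptive fields at fine angles, the opposite of the intended
comparison (a field "the size of an average neuron"). The extended profile
is therefore the one implemented.

## 5. Key-synapse statistics

An ensemble of classifiers (one per train/test split) yields a
classifiers × synapses weight matrix per unit. Key synapses are those whose
mean weight differs from zero after Bonferroni correction: whole
classifiers (rows) are resampled — preserving cross-synapse correlation —
and a confidence interval at level $1 - \alpha/N$ is formed per synapse.
The *studentized* (bootstrap-t) interval is the default: with only ~20
classifiers, the percentile interval's tails reach only ~3.8 standard
errors where the corrected level demands ~4.7, so its realized type-I error
is far above nominal (the percentile variant is retained as an option).
Resolving the corrected $7.6 \times 10^{-5}$ tail requires on the order of
$2 \times 10^4$ resamples. "Key excitatory" means key with positive mean;
unit receptive-field maps deposit weight/(number of MRs) at each MR
location and smooth with a 0.3 mm Gaussian (display only; the smoothing
conserves deposited mass away from the borders).

## 6. The synthetic-data generator

`make_synthetic_neuron()` draws MRs uniformly inside an ellipse (default
semi-axes 2.5 × 1.5 mm, in the range of recorded RF footprints; default
maximal rate 120 Hz, an FA-1 peak-rate scale — at much lower rates the
accumulator model produces almost no spikes per sweep, unlike the bursty
recorded responses the generator stands in for).
`synth_recordings()` simulates the full orientation protocol (train
±22.5°/±45°, cross-validate 0°, test 30° with 7 trials for the
reliability statistic) and derives per-trial variability by Gaussian
spike-time jitter (default sd 2 ms) plus random spike deletion (default
5 %) — deliberately small, as first-order responses show little
variability. What the generator does *not* emulate: drum kinematics
artifacts, electrode noise, skin-mechanics nonlinearity, inter-neuron
parameter correlations. A green test therefore establishes that the
pipeline recovers neurons *of the model class from model-generated data*;
it cannot certify fit quality on real microneurography recordings.

## 7. Numerical and scale choices

* 1 ms simulation grid everywhere; spike trains live on the grid.
* Gaussian rate smoothing truncates at ±6σ; the rate integral equals the
  spike count for spikes ≥ ~4σ from the curve ends.
* The acceptance tests run a deliberately reduced world on one CPU:
  populations of 50–80 instances built from 3–5 base neurons, 20–30 trials
  per orientation, 2–3 repeats, GA populations 20–50. The paper-scale
  protocol (330 neurons, 100 trials, 20 repeats, GA 100) is available
  through the same configuration objects but is hours of compute. The
  qualitative orderings asserted in the acceptance suite (NMDA more
  noise-robust than AMPA; AMPA at 5 ms windows beating unlimited windows at
  θ ≤ 3°; complex receptive fields beating simple ones at θ = 1°) were
  verified to survive this reduction before the tests were frozen. One
  caveat: the reduced task is easier than the full-scale one, so both
  channels sit near ceiling at coarse angles and the AMPA channel is near
  ceiling even at θ = 1°; the NMDA-robustness ordering is therefore
  asserted at θ = 5°, where the slow channel's advantage is expressed, and
  is a weak (sign-level) check at this scale.
* All stochastic stages expand one master seed into named per-stage seeds
  via a fixed integer hash, so every pipeline is bit-for-bit reproducible
  from (population seed, trial seed, GA seed).

## 8. Known limitations

* The CLI `fit` subcommand requires the generator ("truth") model to map
  the admissible MR region; mapping a region from spike CSVs alone is not
  defined here. Library users can pass any `rf_region` to `fit_neuron()`.
* `select_model()`'s 5 % filters are multiplicative and can behave
  surprisingly when the maxima are near zero or negative; the implementation
  uses a one-sided band around the maximum (`x ≥ max − 0.05 |max|`).
* Feature matrices are dense (ticks × neurons × channels per trial);
  paper-scale unlimited-window experiments need several GB of RAM. PSP
  features are computed once per trial and reused across GA evaluations and
  repeats.
* SA-1 neurons (sustained responders) are out of scope.
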