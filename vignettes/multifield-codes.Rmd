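---
title: "Multi-field spatial codes on a linear track: models, decoding and optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-field spatial codes on a linear track}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldcode)
```

## The scientific problem

Hippocampal place cells recorded in very large environments — most
famously bats flying through a 200 m tunnel — carry multiple firing
fields of widely different sizes per neuron: a *multi-scale,
multi-field* (MSMF) place code.  This contrasts both with the classical
single-field place code and with the entorhinal grid code, where each
cell's fields repeat at one fixed module scale.  `fieldcode` implements
four generative network families for a 1-D track so that the accuracy,
energy cost and robustness of these codes can be compared under
identical dynamics and an identical decoder, and so that the network
parameters can be optimized by a genetic algorithm:

* **F-MF** (fixed multi-field): neurons participate with probability
  $P_{att}$ in a fixed hierarchy of line attractors.  Level $i$ holds
  $N_{AL_i}$ equal-width attractors tiling the track contiguously; each
  membership contributes one field whose kernel length constant is the
  attractor's interaction length $L_{int} = 0.05\,|\mathrm{span}|$.
* **D-MF** (dynamic multi-field): field widths are drawn i.i.d. from
  $\Gamma(\alpha, \theta)$ and appended until their cumulative width
  first reaches $\bar\Sigma_{fs}$ (the overshooting field is kept);
  centers are uniform on the track.  Lateral connections are gated by
  field-size similarity, $\min(fs_0, fs_1)/\max(fs_0, fs_1) >
  TH_{fsr}$ (strict), or — for the control mode — created at random
  with probability $P_{fc}$ irrespective of sizes.
* **SSSF**: one line attractor spanning the track, one evenly spaced
  field per neuron, shared $L_{int} = 0.05\,L_{env}$.
* **Grid**: $N_{mod}$ modules of $N^{mod}_{neu}$ neurons; module $m$
  has population spacing $S_m = S^{mod}_{min}\,S_{mod}^{\,m}$, each
  neuron a period $P_m = S_m N^{mod}_{neu}$ and a uniform random phase.
  No lateral connections.

All families share the threshold-linear rate dynamics

$$\tau \frac{dh_i}{dt} = -h_i + \sum_j W_{ij}\, g(h_j) + I_{bck} +
I^{pos}_i(t), \qquad g(h) = \max(h, 0),$$

with the positional drive
$I^{pos}_i(t) = \sum_p I_{pos} e^{-|x_{ip} - \mathrm{pos}(t)|/L_p}$
summed over neuron $i$'s fields.  The source equation prints a positive
exponent; we use the decaying sign, since a kernel growing with
distance is unbounded and contradicts the depicted field shapes.  Each
field's own width serves as its length constant $L_p$: the attractor's
$L_{int}$ for F-MF/SSSF, the sampled gamma width for D-MF, and
$w_{ratio} S_m$ (default $w_{ratio} = 1$) for grid cells, whose field
width the source never states.

Recurrent weights follow the symmetric kernel
$W_{ij} = W_{exc} e^{-|x_i - x_j|/L_{int}} - W_{inh}$, accumulated over
every attractor two neurons share, with the inhibition subtracted once
per connected pair.  For D-MF field pairs, which have no common
attractor scale, we apply the 5% rule at the field scale:
$L_{pair} = 0.05\,(fs_0 + fs_1)/2$.

## Study conditions

The simulated agent traverses a 200 m linear track once, left to right,
at 10 m/s.  Positions are discretized into 400 half-open bins of
0.5 m.  A batch of $n$ runs seeds run $r$ with $\texttt{base\_seed} +
r - 1$; identical parameters and seed rebuild a bit-identical model, so
any result row is reproducible from its manifest.  Twenty runs per
condition (the published protocol) are used for all summary medians;
the one deliberate reduction is the 4,000-neuron original F-MF model,
which we evaluate at 3 runs — its per-run decoding is deterministic
given the seed and its run-to-run spread is tiny, so the median
stabilizes quickly.  The drop-out sweep in the test suite uses a
5-point grid at 10 runs/point for the same reason.

## Decoding and metrics

The source never specifies its decoder, so the package uses the
standard population-vector choice: **maximum cosine similarity** between
the instantaneous rate vector and per-bin templates obtained by
bin-averaging one noiseless calibration traversal driven by the model's
own weights.  Ties break toward the lowest bin; an all-zero rate vector
falls back to bin 1.  Cosine matching makes the decoder invariant to
global rate rescaling, which matters because recurrent excitation can
scale activity up without changing its shape.

Consequences worth being explicit about:

* A noiseless traversal decoded against its own templates can never do
  better than the discretization floor, $\approx L_{bin}/4 =
  0.125$ m of mean error (decoded positions are bin centers).
* The same floor is (nearly) reached by *every* family under noiseless
  conditions, because self-consistent template matching resolves even
  weakly covered track segments.  The published nonzero errors of the
  sparse multi-field models (e.g. 1.148 m for the original 50-neuron
  F-MF configuration) therefore cannot be reproduced by any
  deterministic noiseless decoder that also reproduces the published
  0.000 m of the optimized models; those absolute values carry
  reconstruction uncertainty, and comparisons in this package treat
  them as upper bounds.

Positional error is the time-averaged $|$decoded $-$ true$|$ distance;
batch statistics (median, mean, min, max, SD) are taken over runs.
Fields are extracted from a rate map as maximal contiguous runs of bins
above $\theta_{field}$ (default 0.2) of the neuron's peak rate —
$\theta_{field}$ is unspecified in the source, so it is exposed in the
API and held fixed across all compared models.  Energy consumption is
$C_{eng} = N_{bins} \cdot \bar F_{all}$ with $\bar F_{all}$ the mean
in-field rate over all extracted fields.  Codes are classified SSSF /
SSMF / MSMF from the per-neuron field counts and the modality of the
field-size histogram: bin width $L_{bin}$, light smoothing, peaks with
at least 10% prominence, and "multi-scale" when two peaks at least a
factor two apart survive — a direct operationalization of the
"two separate peaks, one at twice the size" criterion.

## Evolutionary optimization

The genetic algorithm follows the generate → evaluate → select → mate →
mutate loop with elitism.  Fitness is read as

$$f = \frac{e^{-\tilde E^{\mu}_{pos}\, 5 / L_{env}}}{N_{neu}},$$

the only parsing of the printed token order in which the constant 5
rescales the exponent and the neuron count penalizes larger networks
(inert when $N_{neu}$ is fixed).  Selection keeps the top
$\lceil R_{sel} N_{pop}\rceil$ by fitness (stable ties); parents are
drawn fitness-proportionally with replacement; crossover is
single-point at a uniform interior split.  For mutation we apply a
*single* per-parameter gate at $P_{mut}$: each parameter is
independently re-drawn from its discretized range with probability
$P_{mut}$.  A double gate (child-level and then per-parameter, both at
$P_{mut}$) is a possible alternative reading of the procedure, but the
source text — "the parameters chosen to be mutated receive a new,
randomly chosen value" — describes parameter-level choice, and the
squared effective rate of the double gate ($P_{mut}^2 = 0.04$) would
make mutation nearly inert at the stated defaults.  Defaults:
$N_{pop} = 20$, $R_{sel} = 0.2$, $P_{mut} = 0.2$, $EP = 3000$, 20
evaluation runs per genome (all configurable; desk-scale work uses far
fewer epochs and evaluation runs).

## Assumed constants

The source's supplementary parameter tables are not part of its
available text, so the following constants are this package's own
documented defaults (`assumed_constants()`,
`inst/extdata/presets.yaml`):

| constant | default | role |
|---|---|---|
| $\tau$ | 0.1 s | membrane time constant; sets the 0.7 m peak lag at 10 m/s |
| $dt$ | 0.01 s | Euler step; $dt \ll \tau$ and 5 samples per bin |
| $I_{pos}$ | 1 | positional input amplitude (decoder is scale-invariant) |
| $\theta_{field}$ | 0.2 | field-extraction threshold |
| $W_{exc}, W_{inh}$ | 0.2, 0.05 | lateral-weight constants of the "+" variants, all families |
| $I_{bck}$ | 0.1 | constant background during the input-removal test |

The lateral and background constants were calibrated once against the
input-removal experiment: with $W_{exc} = 0.2$, $W_{inh} = 0.05$ the
SSSF line attractor holds its activity bump through a 20 m input gap
(decoding error *decreases* when connections are enabled, the
continuous-attractor signature), while every multi-field preset fails
to hold its bump and its error does not decrease — the qualitative
result the package is designed to reproduce.  Within the window the
scoring target is the last driven position, since an ideal attractor
"stands still" there.

## Numerical choices

* Forward Euler from $h(0) = 0$, input evaluated at the left endpoint
  of each step; no settling-in period.  The integrator refuses
  $dt \ge \tau$ and raises a diverged-simulation error naming the step
  if $h$ becomes non-finite.
* The membrane low-pass trails the moving input by $\le v\tau$ (0.7 m
  measured at the defaults); templates inherit the same lag, so
  self-consistent decoding is unbiased.
* Bins are half-open, 0-based in position ($[i L_{bin}, (i+1) L_{bin})$)
  and 1-based as R indices; the track end maps to the last bin so the
  position-to-bin map is total.
* Attractor member labels are evenly spaced across the span
  (bin-centered, spacing $|\mathrm{span}|/M$) and assigned in random
  order: line attractors need ordered positional labels, while the
  membership itself stays random.
* Eq-style tie at exactly $TH_{fsr}$ does **not** connect (strict
  inequality); lesioned neurons keep their population slot (the
  fitness and energy denominators count them) but lose fields, weights
  and template columns.
* Degenerate inputs are defined, not special-cased: empty attractors
  are skipped, silent neurons decode as all-zero template columns, a
  fully lesioned population decodes to bin 1.

## What the generators do and do not emulate

The builders reproduce the *generative statistics* of the published
models: attractor tilings, gamma field sizes with coverage stopping,
geometric module scales with uniform phases.  They do not emulate
biological variability beyond that — no spiking noise, no variable
running speed, no remapping, no 2-D geometry.  Passing tests therefore
demonstrate that the code families and their comparative ordering
(grid most accurate; multi-field most drop-out-robust; none of the MF
models a continuous attractor) hold under the stated idealized
conditions; they say nothing about real recordings.  Two specific
caveats: the D-MF draw-until-coverage rule yields about 6.3 fields per
neuron at the original gamma parameters, whereas the source reports
7.13 — the discrepancy is inherited from an underspecified sampling
detail and left as-is; and the absolute decoding errors of sparse MF
models are decoder-reconstruction-dependent, as discussed above.

## Known limitations

* Single lap, constant speed; the integration step and lap count are
  assumptions exposed in the run configuration.
* The modality test for MSMF classification is a deliberately simple
  peak count, adequate for the clearly uni/bimodal cases exercised
  here, not a general mixture test.
* Recurrent excitation above the self-sustaining threshold grows
  activity linearly (threshold-linear gain has no saturation); runs
  remain finite over a 20 s traversal but long simulations with strong
  excitation would not.
* GA runs at published scale (3000 epochs x 20 genomes x 20 runs) are
  computationally expensive; the package exposes every knob and the
  test suite validates the optimizer on surrogate fitness landscapes
  plus single full-simulation evaluations instead.

## A worked example

```{r example, eval = FALSE}
env <- make_environment(200, 0.5)
traj <- make_trajectory(env, speed_mps = 10, dt_s = 0.01)

set.seed(1)
model <- build_preset_model("G-Opt-1", env)
sim <- simulate_network(model, traj)
tmpl <- build_templates(model, env, simulation = sim)
positional_error(sim, tmpl)$e_pos_mean

res <- evaluate_batch(function() build_preset_model("G-Opt-1", env),
                      env, n_runs = 20, base_seed = 1)
error_batch_stats(res$e_pos_mean)
```
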