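---
title: "A memory-augmented particle-filter model of gravity adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A memory-augmented particle-filter model of gravity adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(gravadapt)
```

## The problem

When the effective magnitude of gravity changes -- entering orbit, landing,
riding a long-radius centrifuge -- the central nervous system's internal
models of vestibular afference become wrong, and perception of
self-orientation degrades until the internal models re-adapt. Repeat flyers
re-adapt faster to gravity levels they have experienced before, suggesting
that learned sensorimotor states are retained in long-term memory and
recalled when familiar stimuli return.

`gravadapt` implements a computational account of this process. The internal
gravity magnitude is treated as a slowly identified parameter: a population
of *hypotheses* (particles) about `|g|` is maintained, each hypothesis
conditions a vestibular observer model, and the mismatch between actual and
expected afference (sensory conflict) determines each hypothesis's
likelihood. New hypotheses are drawn from a mixture transition kernel
combining a short-term Gaussian search around current hypotheses with a
long-term memory of previously *harmonious* gravity levels.

## Model structure

### The observer layer

Each observer is conditioned on a gravity magnitude `x` and maintains a
perceived gravity up-vector `g_hat` (magnitude pinned to `x`), perceived
linear acceleration `a_hat` and perceived angular velocity `omega_hat`. Its
internal sensor models mirror the afferent dynamics: semicircular canals as
a first-order high-pass on angular velocity (time constant `tau_canal`,
bilinear discretization), otoliths as identity transduction of specific
force. Three conflicts drive the state:

* `e_omega = canal - expected_canal` corrects `omega_hat` (gain `k_omega`);
* `e_a = w * (oto - (a_hat + g_hat))` corrects `a_hat` (gain `k_a`, leak
  `tau_a`);
* `e_f = w * (unit(oto) x unit(a_hat + g_hat))`, the rotational misalignment
  between measured and expected gravito-inertial force, rotates `g_hat`
  (gain `k_f`) and feeds `omega_hat` (gain `k_fomega`).

Both `e_f` pathways are corrective: because `g_hat` is rotated by
`-omega_hat`, the angular-velocity pathway takes `+e_f` while the direct
gravity pathway takes `-e_f`. (With both signs equal the feedback loop is
unstable -- the perceived up-vector flips -- which settles the sign
convention; the gains are stated as positive corrective magnitudes.)

The per-axis weight vector `w` implements differential weighting of the
otolith conflict components. With `w = (1, 1, 1)` the observer's static
equilibrium aligns the expected with the measured GIF exactly, so tilt
perception is veridical at *any* hypothesised magnitude -- no tilt
misperception ever arises at equilibrium. Down-weighting the interaural
component (engine default `w = (1, 0.4, 1)`) makes unexplained otolith
shear resolve into tilt rather than linear acceleration: an observer
conditioned on 1 g exposed to a 4 g roll-tilt stimulus then overestimates
roll by roughly a factor of two (the G-excess illusion), while a matched
observer remains veridical within a few percent. The weight is a
configuration knob, not a fitted quantity.

### The inference layer

For hypothesis `j`, the reduced conflict `e = (||e_a||, ||e_f||,
||e_omega||)` is collapsed into the normalized innovation squared
`eps = e' S^-1 e` and the measurement likelihood

```
p(y | x_j) = (2*pi)^(-3/2) |S|^(-1/2) exp(-eps_j / 2).
```

With bootstrap resampling at every filter step, weights are proportional to
likelihoods (computed in log space and normalized by the maximum log
likelihood, because the density underflows at large `eps`). The posterior is
aggregated on the hypothesis grid and summarized by its MAP, with ties
broken toward the lower gravity value for determinism. The *central
observer* -- the bank observer at the MAP grid value -- supplies the model's
overt percepts and the central NIS.

`S = diag(sigma_a^2, sigma_f^2, sigma_omega^2)` sets how sharply hypotheses
are discriminated, and with it the adaptation rate. The defaults
`(0.03 g, 0.05, 0.02 rad/s)` were chosen by a discrimination argument: with
the default gains a steady magnitude mismatch `dg` leaves an acceleration
conflict of about `0.2 * dg` (the mismatch is partially absorbed by `a_hat`;
the factor is `1 / (1 + k_a * tau_a)`), so adjacent 0.01 g grid bins are
statistically indistinguishable (`eps ~ 0.004`) while a 0.05 g mismatch is
selected against within tens of steps (`eps ~ 0.11` per step). A consequence
worth knowing: the likelihood surface is deliberately near-flat within ~2
grid bins of the truth, so the MAP wanders at bin level (typically within
±0.03 g, occasionally ±0.05 g); summaries therefore use final-window
medians.

### Short-term memory: the jitter search

The history of maximum likelihood is an exponentially weighted average,

```
HML_k = (1 - 1/(1+f)) HML_{k-1} + (1/(1+f)) max_j p(y_k | x_j),
```

and the short-term search is a grid Gaussian centred on each parent with
width `sigma = clip(c_jitter / HML^chi1, sigma_min, sigma_max)`. Sustained
high likelihood keeps `sigma` at its floor (exploitation); a collapse of
likelihoods lets HML decay over a few steps -- single outlier measurements
cannot trigger it -- and the search widens toward `sigma_max`
(exploration). `HML_0` is initialized at the zero-conflict likelihood, its
maximum possible value, so every simulation starts fully adapted to its
initial level.

### Long-term memory: harmonious states

Whenever the central NIS falls below the harmony threshold `nu`, the current
MAP estimate is stored with a timestamp; entries older than the retention
window `t_wind` are pruned. The LTM density puts a point mass of `1/n_wind`
(with `n_wind = t_wind / dk`) on each remembered grid bin, so its total mass
is the fraction of the window spent harmonious. Because the buffer is
time-stamped rather than count-limited, learned states age out even while
the model is exploring, and are unlearned entirely after a full window away.

### The mixture transition kernel

New hypotheses are drawn from

```
p(x' | x) = [ (1-W) p_STM(x' | x; sigma) + W p_LTM(x') ] / normalizer,
W = 1 / (1 + exp(-sigma * chi2)) - 1/2  in [0, 1/2).
```

In exploitation `W` is a fraction of a percent: learned states are sampled
only intermittently (a particle or so per step), at essentially no cost to
tracking. In exploration `W` approaches 1/2, so remembered levels receive
almost equal priority with the local search -- this is the mechanism that
makes re-adaptation to a familiar level nearly immediate while leaving novel
levels to the Gaussian search.

## Default parameters

| parameter | default | units | role |
|---|---|---|---|
| `k_omega`, `k_f`, `k_fomega`, `k_a` | 8, 4, 8, 4 | -- | observer feedback gains (literature-inspired, not fitted) |
| `tau_canal` | 5.7 | model s | canal high-pass time constant |
| `tau_a` | 1 | model s | acceleration-estimate leak |
| `oto_weights` | (1, 0.4, 1) | -- | differential otolith conflict weighting (engine default) |
| `S` | diag(0.03, 0.05, 0.02)^2 | (g, --, rad/s)^2 | conflict covariance: discrimination sharpness |
| `N_s` | 100 | -- | particles |
| grid | [0.05, 5] by 0.01 | g | hypothesis support (excludes 0 g) |
| `noise_power` | 1e-8 | (units)^2 s | sensor white-noise PSD height |
| `f` | 0.8 | -- | HML forgetting factor |
| `chi1`, `c_jitter` | 1, 10 | -- | jitter law (`sigma ~ sigma_min` at the zero-conflict HML) |
| `sigma_min`, `sigma_max` | 0.005, 1 | g | jitter clip bounds |
| `chi2` | 4 | 1/g | LTM weight sigmoid slope |
| `nu` | 2 log 2 | -- | harmony threshold: NIS at which the likelihood halves |
| `t_wind` | 300 | model s | LTM retention window |
| `dt`, `dk` | 0.05, 0.5 | model s | integration and filter steps |

Time is in unitless "model seconds": none of the constants have been fitted
to empirical adaptation time courses, so absolute durations are not claims --
only comparisons between simulations are.

## What the scenario generator emulates -- and what it does not

The canonical stimulus is passive sinusoidal roll tilt at 1 rad/s
(0.159 Hz) with 10 deg/s peak angular velocity, hence 10 deg peak roll, with
step transitions among {0.5, 1, 2, 4} g and no inertial linear acceleration.
(The stimulus is sometimes quoted with a peak of "10 degrees"; the
peak-velocity reading is adopted here, and at 1 rad/s the two coincide
numerically.) Canonical schedules use 100-model-second segments, several
times the observed 1 -> 4 g adaptation time under the defaults, so a learned
state forms before the next transition; the `lifecycle` scenario holds the
second segment for 350 s so the departed level's memory ages past `t_wind`
within the run.

Real vestibular adaptation involves visual and somatosensory channels,
active-motion efference, otolith tilt-translation reinterpretation near 0 g,
and sensory noise whose structure is unknown (modeled here as white with
constant PSD). Passing simulations therefore demonstrate the internal
consistency and qualitative behavior of the mechanism -- likelihood-gated
exploration, memory-gated re-adaptation, G-excess misperception -- not
quantitative predictions for human time courses.

## Numerical choices

* Canal dynamics use the bilinear transform; at 1 rad/s with `dt = 0.05` the
  gain error against the analytic transfer function is below 0.01%.
* Truth kinematics integrate the orientation quaternion with trapezoidal
  body-rate sampling (a left-rule step biases the integrated roll of the
  canonical stimulus by ~0.25 deg) and renormalize every step.
* Likelihoods are evaluated in log space and normalized by the max; the
  density value itself (which may underflow to zero) feeds HML, so a total
  collapse drives `sigma` to `sigma_max` as intended.
* MAP ties break toward the lower gravity value; delta functions in the LTM
  density are single-grid-bin indicators (0.01 g).
* `e_f` is set to zero when either vector norm falls below 1e-9 (relevant
  only near 0 g, which is out of scope).
* Three named RNG streams (noise, resample, transition) are derived from the
  master seed, so toggling LTM or the resampling scheme leaves the noise
  realization fixed; runs are bit-reproducible from `(config, seed)`.
* Resampling is multinomial (bootstrap) by default; systematic resampling is
  available via `engine_config(resample = "systematic")`.
* The exhaustive grid Bayes filter (`grid_bayes_reference()`) emulates the
  particle filter's HML by maximizing likelihood over bins with predicted
  mass of at least `1/N_s` -- the bins an `N_s`-particle ensemble occupies.

## Design choices that were genuinely open

* **Observer variant.** The observer layer is specified here as the minimal
  magnitude-constrained variant with four corrective gains; it reproduces
  every behavior the filter needs (conflict generation, GIF resolution,
  G-excess with differential weighting) without the full machinery of larger
  observer models.
* **LTM stores the central estimate**, not per-particle estimates, gated on
  the central NIS: memory reflects the state the organism actually adopted.
* **One `W` per step**, shared across particles, since HML is defined over
  the whole hypothesis set.
* **Toggling LTM is only statistically neutral before a transition.** While
  the model sits harmoniously at its only learned level, the memory kernel
  re-concentrates a little mass on bins the short-term kernel already
  covers, so individual draws (and the bin-level MAP wander) differ between
  LTM on and off even on shared streams; the trajectories agree to within
  the wander. That small kernel difference is the learned-state sampling
  mechanism itself, so it is not removed.
* **Adaptation metric.** "Steps to reach" counts filter steps until the MAP
  first enters ±0.05 g of the target; readaptation comparisons sum this
  over the revisited-level transitions of a schedule.

## A worked comparison

```{r comparison, eval = FALSE}
sc <- canonical_scenarios(segment = 100)
cmp <- compare_ltm_adaptation(
  sc$relearn_4141, engine_config(), seeds = 1:10,
  transitions = data.frame(at = c(200, 300), target = c(1, 4))
)
tapply(cmp$steps_ltm, cmp$seed, sum) # with memory: a few steps
tapply(cmp$steps_no_ltm, cmp$seed, sum) # without: tens of steps
```

Typical problem sizes: one 400-model-second scenario is 8,000 observer
steps over a 496-bin bank and 800 filter steps, about two seconds of
compute; the paired 10-seed comparison above is forty such runs.

## Known limitations

* Free constants (`S`, `f`, `chi1`, `chi2`, `c_jitter`, `nu`, `t_wind`) are
  plausible placeholders; different values change adaptation speed and
  memory persistence quantitatively.
* Microgravity (0 g) transitions are excluded: near-zero internal gravity
  changes the observer's interpretation of otolith afference qualitatively.
* Only passive vestibular input is modeled; no visual/somatosensory fusion
  or sensory reweighting.
* Per-particle percepts are not merged into multimodal percepts; the central
  observer alone generates perception.
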