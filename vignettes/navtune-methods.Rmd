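---
title: "Models and methods behind navtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind navtune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

navtune analyzes neural population recordings made while a subject drives a
wheelchair around a small room toward a fixed reward dispenser. It asks two
questions of every neuron — does its firing depend on *where* the chair is
(place-cell-like tuning), and on *which way* the head or chair points
relative to the dispenser (direction-like tuning)? — and two questions of
the population: can position and orientation be decoded from it, and is the
tuning stable across days? Because no public recordings accompany this
task, the package ships a synthetic session generator with planted,
known tuning, so that every analysis stage has a recovery oracle and every
statistical claim made by the test suite is checkable against ground truth.

## Session model and covariate geometry

A session is a gap-free sequence of 100 ms bins carrying the chair pose and
per-neuron spike counts. From the pose track we derive the covariates used
throughout: position $(x, y)$ in meters with the origin at the room center,
signed translational velocity $v$ (m/s, along the chair heading), rotational
velocity $\omega$ (deg/s), distance to the dispenser $r$, the room-frame
bearing $\theta$ of the chair from the dispenser, and the two egocentric
dispenser bearings — $\alpha$ relative to the head heading and $\beta$
relative to the chair heading.

Conventions that the data themselves do not fix, chosen once:

* **Frame.** $x$ runs along the 3.5 m room dimension; the dispenser sits at
  the midpoint of the wall at negative $x$, i.e. $(-1.75, 0)$. The printed
  task constants (start points $(0.86, 0.65)$, $(1.0, 0)$,
  $(0.86, -0.65)$; drivable area $3.1 \times 2.4$ m) are consistent with
  this frame but do not determine which wall holds the dispenser; the
  choice is recorded in the geometry object and is configurable.
* **Angles.** Degrees on $[-180, 180)$, positive clockwise from above, so
  that positive $\omega$ means a clockwise turn. All angular arithmetic is
  modular.
* **Differentiation.** $v$ and $\omega$ come from central finite
  differences of the 10 Hz pose track (one-sided at trial edges, never
  across trials); $\omega$ differentiates the unwrapped heading.
* **Binning.** Bins are half-open $[t, t + 0.1)$; spatial bins are likewise
  half-open and anchored at the drivable-area corner.
* **Normalization.** Z-scores use the population (divide-by-$n$) standard
  deviation over the whole session; a silent neuron yields zeros and a
  flag. The 3-point moving average used before mapping is centered, with
  two-point averages at the ends.

Zones are nested circles around the dispenser: the *docking zone*
(default radius 0.9 m), inside which an autopilot parks the chair, and the
*reach zone* (default 0.55 m), inside which the subject reaches for the
reward. Tuning analyses use only pre-docking (navigation-zone) bins; reach
analyses use all bins.

## Synthetic sessions

`simulate_trajectories()` is a noisy proportional-steering controller, not
a behavioral model: each trial starts at one of the three start points
(cycled), wanders through one or two random waypoints, then heads for the
dispenser; on docking-zone entry a deterministic autopilot drives in and
dwells ~2 s near the dispenser. Commands are clipped to the hardware limits
($\pm 0.28$ m/s, $\pm 46$ deg/s) and positions to the drivable bounds. The
defaults were set so that 50 trials cover well over half of the drivable
area at 0.4 m resolution and navigation outnumbers reach bins by roughly
nine to one, matching the task's class imbalance. A `side_bias` knob
emulates the reported tendency of trajectories to stay on their starting
side; no further behavioral realism is claimed — in particular the real
trajectories were produced by a closed-loop brain-machine interface, whose
dynamics we do not model.

`generate_spikes()` draws Poisson counts with log-rate

$$\log \lambda_t = b + g_{pos} G(x_t, y_t) + g_\alpha V(\alpha_t)
  + g_\beta V(\beta_t) + \log(g_{reach}) \mathbf{1}[\text{reach}_t]
  + \rho (y_{t-1} - \bar y),$$

where $G$ is a Gaussian place field and
$V(a) = \exp(\kappa(\cos(a - \mu) - 1))$ a von Mises bump, both normalized
to peak 1 so each gain reads as a peak log-rate increase. The optional lag
term uses the previous *realized* count (a doubly stochastic
autoregression), mimicking spike-count autocorrelation without claiming a
generative model of it. Default conditions: baseline $\log(0.5)$ per bin
(5 Hz), $g_{pos} = 1.5$ with 0.4 m field SD, $g_\alpha = 1.2$ with
$\kappa = 3$, reach gain 2 on 30% of neurons in the study population.
Field centers are drawn outside the docking zone with a 0.25 m wall
margin, since tuning is only estimable where the pre-docking trajectory
samples it. An expected rate above 50 spikes/bin raises an error rather
than silently saturating.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: non-Poisson dispersion, slow drift and
nonstationarity, correlated noise across neurons, conjunctive tuning
beyond the planted forms, and BMI-induced correlations between neural
activity and kinematics (in the real task the neurons *drive* the chair).

## Tuning maps

Position tuning diagrams average z-scored, 3-point-smoothed counts within
5 cm bins. The raw occupancy-masked map is retained for all quantitative
statements; only a display copy is filled (iterative nearest-neighbor
averaging until no missing bins remain) and convolved with a truncated
Gaussian kernel ($7 \times 7$, $\sigma = 3$ bins) whose weights are
renormalized at the edges so constants are preserved. The order —
fill first, then smooth — and the iterative fill rule are conventions;
nothing downstream depends on the display copy.

## Information screening

The plug-in mutual information between a discretized stimulus (position on
a 0.4 m grid, or $\alpha$/$\beta$ in eight 45° bins) and the observed
spike-count alphabet is corrected by the first-order analytic bias
$C_1 = (N_s - 1)(N_R - 1)/(2N\ln 2)$, clamping to zero when the corrected
value is negative or $C_1 > 1$. Significance comes
from circular shifts of the covariate track by a uniform 10–50 s in a
random direction, which preserves both autocorrelation structures; the
add-one convention $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n)$
avoids zero p-values. The FDR family is all neuron-by-covariate tests of
one session, adjusted by Benjamini–Hochberg at 0.05.

The $N_s$ entering $C_1$ is, by default, the full size of the stimulus
discretization (all 0.4 m cells tiling the room; all eight angle bins),
with the alternative — only bins with nonzero occupancy — available as
`ns_convention = "occupied"`. The choice matters: synthetic sessions
visit many boundary cells only a handful of times, and those thinly
sampled cells inflate the plug-in estimate beyond what the occupied-bin
$C_1$ removes, leaving spurious corrected values of order $10^{-3}$ bits
for roughly one untuned neuron in twelve. The full-grid $N_s$ is the
larger, more conservative correction and clamps untuned neurons reliably
while leaving planted tuning untouched (its information is two orders of
magnitude above the extra correction).

Because the corrected statistic is clamped at zero, its permutation null
is mostly a point mass; the test remains exact by exchangeability, but in
an FDR family dominated by strongly tuned neurons the Benjamini–Hochberg
threshold admits null p-values up to a few percent. False-positive rates
should therefore be judged per test rather than per neuron across
covariates.

## Additive tuning model and tuning depth

Counts are regressed on smooth covariate functions with a log link and
quasi-Poisson variance. The full model contains bivariate tensor smooths
for position and kinematics, cyclic smooths for $\alpha$ and $\beta$
(period 360°), an $\alpha \times \beta$ interaction, and smooths of the
previous and next bin's count; with `interactions = TRUE` all remaining
second-order interaction tensors (position-by-kinematics,
position-by-angle, kinematics-by-angle) are added in rank-limited form.
Design choices worth stating:

* The bivariate "main effects" are full tensor products (`te`), not
  interaction-only tensors, because a pure function of $x$ alone must be
  representable inside the position term for the nested-model comparison
  to measure position tuning; interaction terms use `ti` so they exclude
  what the main effects already carry.
* Basis sizes default small ($5 \times 5$ position, $4 \times 4$
  kinematics, 6 per angle) for desk-scale sessions of a few thousand
  bins; all are configurable.
* Smoothing parameters are selected once, on the full model, by fast REML
  (`mgcv::bam`, discretized covariates — deterministic and an order of
  magnitude faster than dense GCV at the same recovered structure), and
  are **held fixed** for the partial refits so the F-test compares nested
  mean structures rather than two independently smoothed models.
* Lag covariates with too few distinct values fall back from a smooth to
  a linear term; degenerate covariates (e.g. a session without rotation)
  are dropped with a warning.

Tuning depth for a covariate group is McFadden's pseudo R-squared
$TD = 1 - D_F / D_P$, where the partial model removes only the group's
main-effect terms (position: the position tensor; orientation: both
angular smooths) and keeps every interaction. The F statistic
$((D_P - D_F)/\Delta df)/\hat\phi$ uses the full-model dispersion and the
difference in effective residual degrees of freedom; because a fully
shrunk smooth can leave $\Delta df$ near zero (which would inflate F out
of a vanishing deviance difference), $\Delta df$ is floored at 1. A
penalized refit can occasionally give $D_P < D_F$; TD is then clamped to 0
and flagged. Neurons with either group significant at $p < 0.005$ receive
the preference of the larger TD (ties by smaller p, then position —
arbitrary and documented); *highly tuned* neurons strictly exceed the
session median of preferred TDs, taken over the assessed neurons'
preferred TDs (the alternative reading — median over all TDs — is noted
as ambiguous and not used).

## Population summaries

A neuron's place field is the set of 5 cm bins, docking zone masked out,
where its fitted position surface strictly exceeds the surface's median;
per-session means of these boolean fields are averaged across sessions
unweighted. Uniformity of the resulting heatmap is tested by a one-sample
Kolmogorov–Smirnov test of its values against the uniform distribution on
$[0, \max]$ — the reference distribution is a convention, since only the
test's name is fixed by the analysis design. Preferred directions are the
argmax of the fitted angular curves on a 1° grid (ties to the smallest
angle; constant curves are excluded with a flag), histogrammed in the
eight 45° bins per session and averaged.

## Cross-session consistency

Stability candidates are neurons highly tuned in at least 70% of sessions
and never re-sorted. Each neuron's trivariate tuning function is the mean
z-scored (smoothed) activity in cells of 0.1 m × 0.1 m × 90° over
$(x, y, \alpha)$; zero-occupancy cells stay missing. The consistency index
between two sessions (or two halves of one) is the mean over neurons of
the Pearson correlation across jointly occupied cells; neurons with fewer
than 20 joint cells are skipped (the threshold is invented — the source
analysis does not say how missing cells were handled). Nulls come from
10–50 s circular shifts of each session's spikes against its covariates;
within- versus between-session indices are compared by a two-sided
Wilcoxon rank-sum test. The histograms use pre-docking bins only,
matching every other tuning analysis; including the docking dwell would
hand any two sessions a large shared block of dispenser-adjacent
structure and defeat negative controls.

The remap condition deserves a caution. Independently re-drawn place
fields in a bounded room are *not* exactly uncorrelated under this
index: interior cells lie near more potential field centers than
boundary cells, so every session shares a faint bowl-shaped expected
profile, worth about +0.02 on the index. Meanwhile the circular-shift
null band tightens without bound as neurons accumulate, so with enough
cells that epsilon is "significant" even though it reflects room
geometry, not tuning stability. The remap generator therefore draws
centers over the whole room (flattening the profile as far as the
geometry allows) and also re-draws preferred directions, whose uniform
average is exactly flat; the meaningful negative-control statement is
that remapping collapses the index to near zero, far below the stable
condition, not that it lands inside the shift-null band.

## Decoding

Decoders are single-hidden-layer networks (tanh hidden, linear output; 30
hidden units for position, 10 for angles) reading five 100 ms bins of
z-scored counts, trained to minimize squared error by Fletcher–Reeves
conjugate gradient (base R `optim(method = "CG", type = 1)`) in short
rounds with early stopping after 15 validation failures. Angles are
decoded as (sine, cosine) pairs. Cross-validation uses 10 contiguous
folds aligned to trial boundaries (no trial straddles folds, which would
leak through the input window); per fold, 5 random restarts compete on a
contiguous 15% validation split and the best evaluates the held-out
trials; the session metric is the median fold MPE (position) or
per-component-averaged Pearson CC (angles). The default architecture is
feedforward; an output-feedback variant appends three past predictions to
the input, trains with teacher forcing and evaluates closed-loop.

Training folds are capped at 3000 bins by a deterministic stride
subsample — a desk-scale choice that leaves recovery intact on the
synthetic sessions used here.

Chance levels: each of (by default) 100 repetitions circularly shifts the
counts by 10–50 s, then permutes the time order of the count vectors
(destroying autocorrelation while preserving the multiset of population
states), retrains, and records the session metric; the empirical 2.5/97.5%
quantiles form the 95% CI. Chance repetitions use a lighter schedule (2
folds, 1 restart) because a decoder trained on de-aligned data converges
to the occupancy-centroid predictor almost immediately; the closed-form
MPE of that predictor is exposed as `centroid_mpe()` and doubles as the
ceiling any useful decoder must beat.

## Reach analysis

Reach bins are those inside the reach zone — a purely geometric label,
roughly one bin in ten. The classifier reduces smoothed z-scored
population activity to its top five principal components (PCA fit on
training folds only; fitting once per session is available as a
compatibility switch but leaks test bins into the projection and is off
by default) and boosts 400 depth-limited decision trees (minimum leaf 20)
with random undersampling of the majority class in each boosting round —
each round trains on the full minority class plus an equally sized
weighted draw of majority bins, and reweights as in discrete AdaBoost
with unit learning rate (the boosting variant is named in the analysis
design but its learning rate is not; 1 is the common default).
Performance is mean Cohen's $\kappa$ over stratified contiguous 5-fold
cross-validation at trial granularity. Peri-event histograms align
smoothed z-scores on each trial's first reach-zone entry (±2 s) and order
neurons by the OLS slope of their trace.

## Problem sizes and determinism

The shipped tests and the acceptance script run everything at desk scale,
chosen as the package's own defaults: 30-trial sessions (~10 minutes of
data), a 60-neuron study population, 200 screening permutations, 20
chance-decoding repetitions, and 1000 consistency permutations (the
minimum at which the add-one p-value can fall below 0.001). Full-scale
settings (1000 screening permutations, 100 chance repetitions) are plain
arguments. Every stochastic step takes an explicit seed and is bit-for-bit
reproducible; GAM fitting, given a session, is deterministic.

## Known limitations

* The synthetic controller produces shorter, more stereotyped trials than
  the real task; consistency indices saturate well below 1 at these
  session lengths because trivariate cells average few samples.
* The quasi-Poisson GAM measures the planted structure through the same
  additive lens the generator uses; real conjunctive or nonstationary
  tuning would lower recovery rates in ways these tests do not probe.
* The KS uniformity tests treat heatmap bins as independent samples, an
  approximation inherited from the analysis design being reproduced.
* Reach classification reads only the top five principal components, so
  its accuracy depends on whether the coherent reach-gain dimension
  survives the projection; across synthetic populations with identical
  planted settings, mean kappa can range from ~0.4 (reach dimension
  crowded out by strong spatial tuning) to ~0.95.
* Percentages reported for the real recordings (fractions of tuned
  neurons per area, session MPEs) are not reproducible here: they depend
  on the unreleased recordings, and the package deliberately reports only
  synthetic-recovery quantities.
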