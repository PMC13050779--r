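---
title: "Methods: biologically informed recurrent inference of directed network coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biologically informed recurrent inference of directed network coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative model
and its assumptions, the training procedure, the statistical layer, the
synthetic cohort generator that makes everything testable, the numerical
choices behind each, and what the package's passing tests do and do not
establish about real recordings.

## The model

The package infers *effective connectivity* — directed, signed influence of
one large-scale brain network on another — from parcel-level source-activity
time series (for example sLORETA source estimates averaged within atlas
parcels, sampled at 1000 Hz). Undirected functional-connectivity measures
cannot distinguish excitatory facilitation from competitive inhibition; a
generative dynamical model with sign constraints can.

Each of the $P$ cortical parcels carries three population states: excitatory
$h_E$, inhibitory $h_I$, and a slow adaptation state $h_A$, all confined to
$[0, 1]$. A fourth state block, $h_{net} \in (-1,1)^K$, summarizes $K = 4$
canonical systems — default mode (DMN), task-positive (TPN), salience (SN)
and a catch-all "Other". The excitatory population of parcel $p$ receives
five inputs:

$$I_E(t) = x_t + W_{out}\,h_{net}(t) + W_{EE}\,h_E(t) + W_{IE}\,h_I(t) - \beta\,h_A(t)$$

observed activity, top-down network drive, recurrent excitation, recurrent
inhibition, and subtractive adaptation. The states evolve by first-order
kinetics with population-specific time constants,

$$\tau_E \dot h_E = -h_E + \sigma(I_E), \qquad
  \tau_I \dot h_I = -h_I + \sigma(W_{EI} h_E), \qquad
  \tau_A \dot h_A = -h_A + h_E,$$

with $\sigma$ the logistic sigmoid, while the network state is a recurrent
nonlinear update driven by the fixed anatomical projection $W_{in}$
(row-normalized membership, so a network signal is the mean of its member
parcels):

$$h_{net}(t) = \tanh(W_{in} x_t + W_{net}\, h_{net}(t-1) + b_{net}).$$

The $K \times K$ matrix $W_{net}$ is the central interpretable output: entry
$(i, j)$ is the directed influence of network $j$ on network $i$, free of
sign constraints (networks mix excitatory and inhibitory populations).

Biological structure is enforced architecturally:

* **Dale's law** — $W_{EE}, W_{EI} \ge 0$, $W_{IE} \le 0$, elementwise.
* **Physiological time constants** — $\tau_E \in [5, 30]$ ms,
  $\tau_I \in [10, 100]$ ms, $\tau_A \in [50, 500]$ ms, per parcel, with
  inhibitory kinetics initialized slower than excitatory.
* **Sparse, local wiring** — binary masks retain 30% of connections
  (diagonal always kept as local recurrence); when parcel coordinates are
  supplied, retention probability decays with distance, and the L1 penalty
  can be distance-weighted.

### Numerical choices

*Discretization.* Forward Euler with a fixed step of $dt = 1$ ms (one sample
at 1000 Hz). Each population update is then a convex combination
$h \leftarrow (1 - dt/\tau)h + (dt/\tau)\,u$ with $u \in [0,1]$, so states
provably stay in $[0,1]$ whenever $dt/\tau \le 1$; the constructor and
`birnn_step()` reject configurations violating that bound. Within a step the
three population updates all read the time-$t$ states (simultaneous update),
and $I_E$ uses the previous network state; $h_{net}$ is then refreshed from
the current sample. The continuous-time equations do not fix this ordering;
the simultaneous convention was chosen because it makes the step a textbook
Euler map with the stability guarantee above.

*Observation readout.* $h_E$ is sigmoid-bounded while source amplitudes are
not, so the one-step prediction of the observed signal is a per-parcel
learnable affine readout $\hat x_{t+1} = g \odot h_E(t+1) + c$. Each parcel
series is z-scored before training (using training-split statistics only) so
the readout starts near identity and the mean-squared error is comparable
across parcels.

*Top-down feedback.* The published description constrains the feedback
pattern to be uniform within a network; the package implements
$W_{out} = \text{pattern} \times \text{diag}(g_{net})$ with one learnable
nonnegative gain per network — uniform contribution preserved, amplitude
flexible.

## Training

`train_birnn()` fits each subject and condition independently by next-step
prediction: $L = \mathrm{MSE} + \lambda\, R_{bio}$, where $R_{bio}$ sums
squared Dale violations, squared time-constant excursions, and an
L1 penalty on all coupling matrices ($\lambda_{L1} = 0.001$, optionally
distance-weighted). Defaults follow the published recipe: AdamW at learning
rate $5\times10^{-4}$ with weight decay $10^{-5}$, up to 150 epochs,
reduce-on-plateau scheduling (patience 15, factor 0.8), and early stopping
(patience 20) restoring the best validation checkpoint.

Choices the recipe leaves open:

* **Validation split** — chronological 80/20 (final 20% held out), avoiding
  leakage through temporal autocorrelation.
* **Gradient truncation** — backpropagation through time in windows of 200
  samples with the recurrent state carried across windows. Windows are
  processed in chronological order: carrying state and shuffling windows are
  mutually exclusive, and the carried state is the substantive ingredient
  (it preserves slow dynamics across window boundaries).
* **Constraint mechanism** — after *every* optimizer update the parameters
  are projected back onto the constraint set (wrong-signed couplings clamped
  to zero, masked entries re-zeroed, time constants clipped, $\beta$ and the
  feedback gains kept nonnegative). Compliance therefore holds exactly at
  every epoch, which the training history records
  (`dale_violations`/`tau_violations` columns, identically zero).
* **Improvement tolerance** — a relative validation-loss decrease greater
  than $10^{-4}$ counts as improvement for both the scheduler and early
  stopping.
* **$\lambda$ (`bio_lambda`)** — 1.0 by default, so the L1 coefficient on
  couplings is exactly 0.001.

The rollout and the window gradients are computed in compiled code
(RcppArmadillo); the analytic backward pass is verified against central
finite differences to $10^{-5}$ in the test suite, and the compiled rollout
against a pure-R composition of `birnn_step()`.

## Group statistics

`extract_network_connectivity()` copies the fitted $W_{net}$ with its
(target, source) orientation. `group_connection_tests()` runs a two-sided
one-sample t-test per directed coupling across subjects and applies
Benjamini–Hochberg FDR over the 16 couplings within each condition
(`benjamini_hochberg()` wraps `stats::p.adjust(method = "BH")`; the test
suite checks it against a brute-force step-up enumeration). Degenerate cells
are handled explicitly: an all-zero cell gets $t = 0, p = 1$ by convention;
a constant nonzero cell is flagged `degenerate` with the limiting $p = 0$
rather than failing.

`imagery_regression()` relates per-subject coupling weights to a behavioral
covariate (e.g. a 16-item imagery-vividness questionnaire, totals 16–80).
"Robust non-linear regression" is implemented as the Spearman rank
association with $R^2 = r_s^2$ — the variance in score ranks explained by a
monotone transform of the weights. A flexible monotone smoother was rejected
deliberately: at $n = 15$ an isotonic fit to pure noise reports substantial
$R^2$, while $\mathbb{E}[r_s^2] \approx 1/(n-1) \approx 0.07$ under the
null, which the calibration test verifies. Ordinary least squares is
available via `method = "ols"`. Families of couplings tested together are
corrected by the Hochberg step-up procedure, the standard referent of the
compound name "Simes–Bonferroni".

## Granger baseline

`pairwise_granger()` implements the classical unsigned baseline on the
4-network series: for each ordered pair and each lag $k = 1..10$, restricted
(own $k$ lags + intercept) and full (+ source's $k$ lags) autoregressions
are fit by least squares on identical target samples, and the joint
F-statistic with $(k,\; T_{eff} - 2k - 1)$ degrees of freedom is recorded;
the minimum-p lag is selected per pair. Diagonal self-connections are
undefined and set to zero. Min-p selection across lags inflates the type-I
error and is reproduced as published; `keep_all_lags = TRUE` exposes the
per-lag table for anyone who wants to correct it. The implementation is
cross-checked against `lmtest::grangertest()` in the tests; F statistics are
affine-invariant and blind to coupling sign — which is exactly the contrast
the signed model is meant to resolve.

## The synthetic cohort generator

No public recording accompanies this model family, so the package ships a
generator that emulates the study conditions: 15 subjects, 46 bilateral
parcels in 4 networks, one recording per condition, simulated from the
model's own forward dynamics under known sparse Dale-compliant connectivity
with condition-dependent network templates, per-subject coupling jitter
(SD 0.2), and additive white observation noise. The packaged 46-parcel
membership table is a synthetic stand-in (the published atlas table is not
deposited); user tables are accepted in the same two-column format.

Design choices, and why:

* **Closed-loop simulation.** The model is driven by the observation it
  predicts, so generation closes the loop: the affine readout of $h_E$ plus
  noise is fed back as the next sample. Simulated data therefore carries
  exactly the temporal dependence the model assumes.
* **Excitation–inhibition limit cycle.** Ground-truth parcel couplings are
  drawn strong enough (with slightly stronger delayed inhibition and slow
  adaptation) that the populations generate self-sustained broadband
  fluctuations rather than relaxing to a fixed point. A quiescent truth
  would produce data with no dependence structure to recover.
* **Calibrated operating point.** Damped pilot rollouts center the readout
  per parcel and set $b_{net}$ to cancel the mean network input. Without
  this, any DC offset pins $\tanh$ network states at saturated attractors
  where the coupling has no dynamic footprint. Rescaling the loop to unit
  observation variance instead is not possible: the required feedback gain
  makes the mean dynamics unstable and saturates the system.
* **Relative observation noise.** `noise_sd` is interpreted relative to the
  per-parcel noiseless signal SD (measured during calibration), i.e. as a
  noise-to-signal ratio — equivalently the noise SD on the standardized
  scale the model trains on.
* **Within-network parcel wiring.** Ground-truth parcel coupling is confined
  to network-diagonal blocks; cross-network interaction is routed
  exclusively through $W_{net}$, which is this model family's own structural
  hypothesis. Dense cross-network parcel wiring instead synchronizes all
  parcels into one global mode that swamps the network coupling's footprint.
* **Benchmark template.** The parameter-recovery template plants six strong
  cells ($|w| \ge 1$, mixed signs): four marginal (+1.0) self-loops, which
  act as near-critical slow integrators whose fluctuations survive the
  excitatory populations' low-pass filtering, plus two negative cross
  couplings. Supercritical self-loops pin at saturated attractors and
  rotational cross-structure oscillates at the sample rate; both leave no
  recoverable footprint. The task/rest templates mirror the qualitative
  pattern reported for real encoding-task EEG (salience facilitation of both
  systems, task-positive inhibition of the default mode that strengthens at
  rest, and a sign flip of the DMN→SN influence between states) at
  magnitudes on the order of reported group means; they are template
  choices, not reproduction targets.

The covariate generator mixes standardized coupling values with independent
noise in exact proportion to a target correlation, rescales to a typical
population distribution (mean 55.5, SD 11), and discretizes into the 16–80
range; discretization attenuates the realized correlation slightly.

## Problem sizes

The test suite and the acceptance script run reduced-scale versions of the
study conditions, chosen as the smallest sizes at which each property is
meaningfully exercised: unit tests use 6–12 parcels and 600–1200 samples;
the constraint-preservation check trains one full 46-parcel subject at
6,000–10,000 samples; parameter recovery uses a 5-subject, 46-parcel cohort
at 3,000 samples per recording; Granger calibration uses 1,000 null
replicates at 500 samples; the group-test recovery simulation uses 200
replicates of 15-subject cohorts sampled directly at the statistics layer.

## What passing tests do and do not show

The generator produces data from the model's own dynamics with white
observation noise. Passing tests therefore establish internal correctness —
the dynamics, gradients, constraint projections, statistics and baseline do
what they claim, deterministically under a seed — and end-to-end behavior
under a best-case generative match. They do not establish that real
source-localized EEG satisfies the model's assumptions: real data has
volume-conduction leakage between parcels, non-stationary artifacts,
frequency-structured (non-white) noise, and no guarantee that cross-network
dependence is carried by four tanh network states.

### A known identifiability limit

One honest negative result from the package's own simulations deserves
emphasis. With everything above in place, the fitted $W_{net}$ reliably
recovers the *presence* and rough pattern of strong planted couplings
(group-level pattern correlation above 0.5 in the recovery benchmark), but
the *sign of individual cross-network cells* is not reliably identified:
planted inhibitory couplings often recover near zero or weakly positive.
Three ingredients conspire. First, per-parcel standardization plus the fixed
unit coefficient on $x_t$ in $I_E$ means the generative parameters are not
the best-fitting parameters of the trained class — a model initialized at
the ground truth keeps the planted structure but fits the standardized data
markedly worse than a freshly trained one. Second, the network means that
drive the four $h_{net}$ components share a dominant common mode, so
individual couplings are nearly collinear routes to the same predictive
signal. Third, the L1 penalty under an adaptive optimizer prunes whichever
collinear route carries the weaker gradient, and the sign of the surviving
route is not anchored. The group-level pattern, the constraint guarantees,
and the unsigned baseline contrast all remain informative; per-cell sign
claims at this cohort scale should be treated with the same caution the
small-sample caveats in the source literature already urge.

## Serialization

Checkpoints (`write_birnn_params()`/`read_birnn_params()`) and cohort
exports are plain JSON and CSV: human-readable, diffable, and round-tripped
bit-exactly by the test suite.
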