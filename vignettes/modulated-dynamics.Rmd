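---
title: "Modulated mesoscale network models: model, fitting procedure, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulated mesoscale network models: model, fitting procedure, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`modmindy` fits a biologically constrained recurrent network model of
mesoscale brain activity to regime-labeled multichannel recordings. The
latent state $x_t \in \mathbb{R}^n$ stacks excitatory populations first and
paired inhibitory populations second, and evolves by the discrete update

$$
x_{t+1} - x_t \;=\; (W \odot \Gamma_{i(t)})\,\tanh(S \circ x_t + V)\;-\;D
\circ x_t\;+\;C\;+\;\epsilon_t, \qquad \epsilon_t \sim N(0, Q),
$$

observed through a lead field,

$$
y_t = H x_t + \nu_t, \qquad \nu_t \sim N(0, R).
$$

Here $W$ is the baseline connectivity, common to all dynamical regimes, and
$\Gamma_i = u_i v_i^\top$ is a nonnegative rank-1 *modulation matrix*, one
per labeled regime $i \in \{1,\dots,m\}$, that rescales connections
element-wise. The rank-1 form encodes the assumption that neuromodulation
acts in a spatially diffuse, multiplicatively separable way; nonnegativity
guarantees the modulation can change a connection's strength but never its
sign. The remaining parameters are the per-population leak $D$, the group
sigmoid slopes $S = (S_{exc}, S_{inh})$, the sigmoid offset $V$, and the
bias $C$.

Dale-type sign structure is imposed on $W$: the excitatory-source blocks
$W_{ee}$ (E$\to$E) and $W_{ei}$ (E$\to$I) are nonnegative, with a fixed
random mask holding 75% of their off-diagonal entries at exactly zero; the
inhibitory-source blocks $W_{ie}$ and $W_{ii}$ are nonpositive and diagonal
(inhibitory projections are local). Because inhibitory populations are
believed not to generate fields measurable at the scalp, the columns of $H$
over inhibitory populations are zero — inhibitory activity is latent in the
strictest sense.

### Sign convention of the leak

$D$ is stored as positive magnitudes and applied as $-D \circ x$. Standard
leak magnitudes near 0.65 (excitatory) and 0.8 (inhibitory) then give the
stable contraction $x \mapsto (1-D)x$ with $1-D \in (0,1)$; applying the
same magnitudes with a positive sign would multiply the state by ~1.65 per
step and diverge immediately for every parameter draw of interest, so the
leak reading is the only self-consistent one. The package validates this
with a two-population stability check in its test suite.

## Dual estimation

Only $y_t$ is observed and $H$ is not invertible ($n = 2\,\times$ channels),
so states and parameters must be estimated together. Each fitting iteration:

1. draws a uniformly random window of `kalman_window_len` samples (windows
   straddling session boundaries are excluded when boundaries are known);
2. runs an **extended Kalman filter** over the window — predict with the
   modulated update (the modulation matching each timestep's label), linearize
   the Jacobian $I + (W\odot\Gamma_i)\,\mathrm{diag}(s(1-\tanh^2)) -
   \mathrm{diag}(D)$ at the current filtered mean, correct through $H$;
3. rolls the model forward **noiselessly** from the last filtered state over
   the next `free_sim_horizon` samples (free simulation) and scores the
   forecast against the held-out observations;
4. backpropagates the combined error into every learnable parameter and
   takes a NADAM step;
5. projects the parameters onto the constraint set (sign clamps, sparsity
   mask, inhibitory-source diagonality, nonnegative modulation factors,
   covariance floors, and the exact all-ones reset of a pinned baseline
   modulation).

The filter is initialized per window with $x_0 = H^+ y$ (Moore–Penrose
pseudo-inverse; inhibitory entries start at 0) and $P_0 = I$.

### The combined error

The default objective is the **whitened innovation criterion** — the
Gaussian filtering negative log-likelihood $\sum_t e_t^\top S_t^{-1} e_t +
\log\det S_t$ over the window, where $e_t$ is the innovation and $S_t$ its
predicted covariance — plus `fs_weight` times the squared forecast error of
the free simulation. Two design findings from the package's own recovery
experiments motivated the defaults:

* Whitening matters. The raw squared innovation norm weights channels and
  directions by their raw variance, and systematically under-identifies the
  weakly excited directions associated with inhibitory pathways; the
  likelihood weighting recovers the excitatory-to-inhibitory block markedly
  better.
* The free-simulation term is informative but biased. A noiseless rollout of
  the *true* parameters is not the conditional mean of a noisy nonlinear
  system ($E[\tanh(x)] \neq \tanh(E[x])$), so long horizons with large
  weight pull the fit away from the generating parameters. A short horizon
  (default 8 samples) at modest weight (default 0.1) retains the multi-step
  dynamical constraint without letting the bias dominate.

### Exact gradients

All gradients are computed by a hand-derived reverse-mode pass through the
*entire* filter recursion — the mean update, the covariance propagation, and
the gains — and through the rollout, implemented in compiled code
(RcppArmadillo). Holding the gains fixed during backpropagation (a common
truncation in dual-EKF practice) was tried first and produced gradient
errors of 5–180% against central finite differences; the exact adjoint
agrees to ~1e-8 relative error, verified in the test suite for every
parameter including the noise covariances. The only non-differentiated
pieces are a constant 1e-10 innovation jitter, a rare fallback
regularization of a numerically singular innovation covariance, and the
window's $x_0$ anchor.

Noise covariances are learned (when `learn_noise = TRUE`) as diagonal
matrices through log-parameterized entries floored at 1e-6; the
log-determinant term of the whitened criterion keeps them anchored. The
lead field can be learned (`learn_H`) but is fixed by default, since it is
either known by construction or supplied by the experiment.

### Optimization schedule

NADAM ($\beta_1 = 0.9$, $\beta_2 = 0.999$) with a cosine learning-rate decay
from `learning_rate` (default 0.01) to 5% of it across `max_iterations`
windows. Two stabilizers proved important at small problem sizes:

* *Scalar damping.* The physiological scalars $D, C, S, V$ start at standard
  values and receive `scalar_lr_frac` (default 0.1) of the learning rate.
  When they adapt as fast as the weights, unobserved inhibitory populations
  can re-parameterize into predictively equivalent but structurally
  scrambled circuits (e.g. operating on the opposite branch of the
  sigmoid), which destroys interpretability without reducing the error.
* *Tail averaging.* The returned estimate averages the parameter iterates
  over the final `average_tail` fraction (default 30%) of iterations,
  damping the stochastic bounce induced by random window selection.

Convergence is declared when the exponentially smoothed (half-life 50
iterations) combined error changes by less than `convergence_tol`
relatively between checks every 50 iterations; otherwise the loop stops at
`max_iterations`. On persistent divergence (50 consecutive non-finite
windows) the last stable parameters are returned with a warning.

### Identifiability and gauge fixing

The factorization $W \odot \Gamma_i$ is structurally unidentified along a
rank-1 diagonal *gauge*: for any positive vectors $a, b$, replacing $W$ by
$W \odot ab^\top$ and every $u_i, v_i$ by $u_i/a, v_i/b$ leaves all
effective weights unchanged. Stochastic optimization diffuses along this
flat direction, silently degrading the interpretable decomposition. The fit
therefore re-normalizes after every step: the occupancy-weighted mean of
the modulation factors across regimes is pinned to 1 (the compensating
scale moves into $W$) — matching the generative convention that modulations
hover around 1 — with weights proportional to each regime's share of
samples, so that a rarely visited regime's weakly constrained factors
cannot pollute the shared connectivity. When a baseline regime is pinned to
$\Gamma_1 = \mathbf{1}\mathbf{1}^\top$ (as in resting-baseline designs) the
gauge is already fixed and the normalization is skipped.

A second, softer near-degeneracy involves the unobserved inhibitory
populations: each population's incoming scale ($W_{ei}$ row) can be traded
against its outgoing diagonal coupling with only the sigmoid's curvature
opposing. The scalar damping above, plus initializing the inhibitory
couplings at model-class scale rather than near zero (a population whose
I$\to$E route starts at ~0 carries almost no gradient and can stay pruned),
are what keep this direction anchored.

## The synthetic-data generator

The generator draws ground-truth models from the standard study conditions
and forward-simulates them, so that fitting can be validated against known
parameters:

| quantity | law |
|---|---|
| sparse part of $W_{ee}$, $W_{ei}$ | $(16/20)\,U(0,1)^3$ elementwise |
| low-rank part | $B_1 B_2^\top$, $B_\cdot \in \mathbb{R}^{n \times \lfloor n/4\rfloor}$, entries $U(0,1)^3 + 0.2\,U(0,1)$ |
| diagonal self-connections | $U(0,1)$ |
| $W_{ie}$ diagonal | $-U(0.3, 1)$ |
| $W_{ii}$ diagonal | $-U(0, 1)$ |
| slopes $S_{exc}, S_{inh}$ | 2.5, 1 |
| leaks $D_{exc}, D_{inh}$ | $0.65 + 0.02U$, $0.8 + 0.02U$ |
| offset $V$, bias $C$ | 0 |
| lead field $H_{exc}$ | entries $N(0,1)$; inhibitory block 0 |
| process noise $Q$ | $0.25\,I$ |
| measurement noise $R$ | $\mathrm{diag}(0.2 + 0.1U)$ |
| regimes | $m = 3$; $\mu_i \sim N(1, 0.1)$; fair coin between a uniform branch ($\sigma_i \sim N(0.4, 0.1)$, $g \sim U(\mu_i \pm \sigma_i/2)$) and a normal branch ($\sigma_i \sim N(0.05, 0.01)$, $g \sim N(\mu_i, \sigma_i)$); $\Gamma_i = gg^\top$, negatives clipped to 0 |
| regime switching | sticky chain $A \propto 0.999I + (0.001/m)(\mathbf{1}\mathbf{1}^\top - I)$, rows renormalized; $\pi$ uniform |
| duration | $T = 20{,}000$ samples at 250 Hz (80 s) by default |

Three readings deserve a note, because the conventions are not
self-explanatory:

* $U(0,1)^3$ is read as the elementwise cube of uniform draws — the standard
  way to skew weight magnitudes toward small values — and $16/20$ as a
  scalar prefactor.
* The sticky transition matrix as written above has rows summing to
  $0.999 + 0.001(m-1)/m \neq 1$; rows are renormalized (a warning is logged
  at construction), which preserves the near-diagonal structure.
* The covariance naming is fixed as $Q \to \epsilon$ (process, $0.25I$) and
  $R \to \nu$ (measurement, uniform diagonal), the pairing consistent with
  the fixed real-data settings $Q = 0.25I$, $R = 1.2I$.

The $W_{ie}$ magnitudes are drawn bounded away from zero. This is a
well-posedness requirement of the *validation design*, not of the model: an
inhibitory population whose only route to the observed excitatory
populations has weight ~0 is unidentifiable in principle — no estimator
could recover its $W_{ei}$ row — and recovery scores would then measure the
draw of the ground truth rather than the quality of the fit. The bound
(0.3) is exposed in `synth_config()`.

By default `generate_dataset()` also resamples the regime sequence until
every regime appears at least 100 times: a recovery study cannot probe a
modulation that is never active, and the sticky chain makes missing regimes
likely at short $T$.

### What the generator does and does not emulate

The synthetic recordings share the real-data geometry (20 channels at
250 Hz in the default configuration, regime labels per sample) and the
model's own dynamics, but they are *self-consistent by construction*: the
fitted model class contains the generating process. Passing recovery tests
therefore demonstrates that the estimator solves the inverse problem —
including its partial observability and its factorization structure — not
that real EEG obeys this model. Real recordings add model mismatch
(unmodeled physiology, artifacts, volume conduction beyond the assumed lead
field, non-Gaussian noise), which the synthetic suite deliberately does not
imitate; no attempt is made to match realistic EEG spectra.

## Preprocessing of real recordings

`preprocess()` implements the standard pipeline for regime-labeled EEG:
zero-phase (forward-backward) Butterworth bandpass, default 0.5–15 Hz at
order 4; per-channel median subtraction; division by the per-channel mean
absolute deviation; concatenation of per-regime sessions with a label per
sample and recorded session boundaries (the fit excludes windows straddling
a boundary, since the model assumes within-regime continuity and
concatenation seams are artifacts). Zero-phase filtering is chosen because
phase lag would distort the very dynamics being fitted. Constant channels
are centered to zero and left unscaled with a warning rather than divided
by a zero deviation. `build_lead_field()` and `build_fixed_noise()` supply
the fixed $H = [I - 0.05\,\mathbf{1}\mathbf{1}^\top \mid 0]$, $Q = 0.25I$,
$R = 1.2I$ used for channel-resolved fits.

## Evaluation machinery

* `masked_correlation()` — Pearson correlations between true and fitted
  parameters over the entries that survive the true sparsity mask
  (structural zeros are identical on both sides and would inflate the
  score; a flag restores the all-entries variant). The full-$W$ vector
  additionally includes the inhibitory-source diagonals. Modulation
  matrices are compared on their effective excitatory sub-blocks. Pearson
  correlation is deliberately scale-invariant: the factorization leaves an
  overall scale per factor unidentified.
* `split_half_reliability()` — within- versus across-subject correlations of
  half-data fits, all four half-pairings per subject pair, compared by a
  one-sided Wilcoxon rank-sum test (the specific test is a package choice;
  medians and the full distributions are returned alongside).
* `modulation_impact()` — $W \odot (\Gamma_b - \Gamma_a)$, the signed change
  in effective connection strength between regimes, with row-wise
  (post-synaptic) aggregation. Exactly antisymmetric in its arguments.
* `gamma_value_summary()` — per-regime fractions of modulation entries in
  $[0,1)$ versus $>1$ (entries exactly 1 count as *not* greater, matching
  the strict reading) and quartiles, over the effective entries.

## Validation scale and reproduction

The package's recovery study runs at a reduced scale chosen so that a full
two-architecture comparison completes on a single CPU core in minutes:
$K = 8$ ground-truth models with 10 excitatory + 10 inhibitory populations,
10 channels, $T = 5000$ samples, $m = 3$ regimes (modulated suite) or
$m = 1$ with the baseline modulation pinned (unmodulated suite), 8000
fitting windows per model, true $H, Q, R$ supplied as known constants of
the experiment and all other parameters from random initialization, the
fit's sparsity mask shared with the truth. `scripts/acceptance.R` runs
exactly this study end to end; the test suite runs a 2-model smoke version
plus a miniature (4+4 populations, $T = 2000$) recovery check. At this
scale the unmodulated full-$W$ median correlation sits near 0.96 and the
modulated near 0.95–0.97, with the excitatory-to-inhibitory block the
noisiest — consistent with it being carried entirely by latent populations.

Supplying the true covariances as fixed constants (rather than learning
them from the truth as initialization) is the one simplification relative
to the full dual-estimation protocol in the reduced-scale study; with noise
learning enabled the same suite loses roughly 0.05–0.08 of median
excitatory-to-inhibitory correlation and the other blocks are unchanged.

## Known limitations

* Regime labels are required input; inferring *when* regimes switch is out
  of scope by design.
* Filtering only — no backward (RTS) smoothing pass is applied to the state
  estimates.
* The modulation decomposition is reported in the unit-mean gauge (or the
  pinned-baseline gauge); per-entry modulation values are only meaningful
  relative to that convention.
* The estimator's objective is predictive; parameters that barely influence
  predictions (e.g. connections into a weakly coupled latent population)
  are recovered with correspondingly low precision, and at short $T$ an
  equal-loss flat valley can retain a visible bias on the
  excitatory-to-inhibitory block.
* `Wie`/`Wii` magnitudes, the diagonal self-connection law, and the exact
  meaning of the cubed-uniform notation are generator conventions of this
  package (documented above), exposed in `synth_config()`.
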