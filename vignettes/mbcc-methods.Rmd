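---
title: "Methods: multi-band collaborative classification"
author: "mbcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-band collaborative classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This note documents the mathematical model implemented by `mbcc`, the
role of every major parameter, what the synthetic generator produces,
the numerical choices made in the solvers — including two places where
the package deliberately reformulates the projection step, and why —
and the known limitations.

## The model

The classifier targets multi-frequency-band signal data, the canonical
case being EEG emotion recognition: each trial (epoch) is observed as
$M$ feature vectors $z^m \in \mathbb{R}^d$, one per frequency band
(e.g. log band power per channel in the delta, theta, alpha, beta and
gamma ranges). Bands of the same trial are views of the same underlying
event, so they share structure, but each band also carries its own
discriminative information. The model couples the bands through two
jointly learned objects:

1. **A shared-plus-specific projection.** Band $m$ is mapped to a
   common $p$-dimensional subspace by
   $G^m = (1 - \sigma)\, G_0 + \sigma\, \tilde G^m$, where $G_0 \in
   \mathbb{R}^{d \times p}$ is shared across bands, $\tilde G^m$ is
   band-specific, and $\sigma \in [0, 1]$ mixes the two. $\sigma = 0$
   forces one common subspace; $\sigma = 1$ decouples the bands.

2. **A shared class-structured dictionary.** A single dictionary
   $D = [D_1, \dots, D_C]$ with `atoms_per_class` unit-norm atoms per
   class is learned for all bands. A projected sample is coded against
   the projected dictionary by ridge regression, and discrimination is
   measured on *coding-reconstruction residuals*: with codes $a$ for
   sample $z$, the within-class residual keeps only the coefficients on
   the sample's own class block ($\delta$-masked), the between-class
   residual keeps the coefficients on all other blocks ($\xi$-masked).
   Summed over samples and bands these give within- and between-class
   reconstruction scatter matrices $W_w^m$, $W_b^m$ in feature space,
   and the Fisher-style training criterion asks for projections under
   which own-class reconstructions are accurate and cross-class
   reconstructions are not.

Training alternates three steps until the objective stabilizes:
per-band ridge coding against the projected dictionary; a trace-ratio
solve for the projections given codes and dictionary; a backtracking
gradient step on the dictionary given codes and projections. The
monitored objective is

$$
J = \frac{\sum_m \| (G^m)^\top (Z^m - D\,\delta(A^m)) \|_F^2}
         {\sum_m \| (G^m)^\top (Z^m - D\,\xi(A^m)) \|_F^2
          + \alpha \sum_m \| G_0^\top Z^m \|_F^2},
$$

a within/between residual ratio with a variance-retention reward in
the denominator (see below for why the reward sits there).

**Classification** is per-band nearest-subspace on residuals: band $m$
of a test sample is projected by $G^m$ and each class is scored by the
least-squares residual of reconstructing it from that class's
projected sub-dictionary; each band votes for its residual-minimizing
class and the final label is the majority vote, with vote ties broken
by the smallest accumulated winning residual. `fit_opfddl()` provides
the predecessor baseline: fully independent per-band projections (no
shared component, no variance term) with the same dictionary machinery,
so the contribution of cross-band coupling can be measured directly.

## The projection step, and why it is reformulated

Given scatters, the projection step is a trace-ratio problem: minimize
$\operatorname{Tr}(G^\top A\, G) / \operatorname{Tr}(G^\top H G)$ over
orthonormal $G$. `solve_projection()` implements the standard scalar
reduction: $F(\rho) = \min_{G^\top G = I}
\operatorname{Tr}(G^\top (A - \rho H) G)$ is the sum of the $p$
smallest eigenvalues of $A - \rho H$, it is concave and non-increasing
in $\rho$, and its root is the optimal ratio. The iteration is the
exact Newton update $\rho \leftarrow \rho + \lambda_\rho
F(\rho)/\operatorname{Tr}(G^\top H G)$ (damped by `lambda_rho`),
safeguarded by bisection whenever a step would leave the current
sign-change bracket, so convergence does not depend on the starting
point. Eigenvectors carry a deterministic sign convention, making the
whole fit reproducible bit-for-bit.

Two natural formulations of the full projection step turn out to be
ill-posed, and the package replaces both. These are design decisions,
so they are spelled out here.

**First: one stacked relaxation degenerates; solve the components
separately.** Writing the step as a single eigen-problem on stacked
operators, with orthonormality imposed only on the stacked
$[G_0; \tilde G^1; \dots; \tilde G^M]$, admits stacked directions whose
*effective* per-band projections $(1-\sigma)G_0 + \sigma \tilde G^m$
are numerically zero — both scatter energies vanish there — and it can
concentrate all $p$ columns in whichever single band offers the best
ratio, leaving other bands with rank-deficient projections. The model
actually requires every per-band projection to be well-conditioned, so
the package solves the constrained components separately, each a
well-posed trace-ratio problem: $G_0$ from the summed-over-bands
scatters, each $\tilde G^m$ from band $m$'s own scatters. The specific
bases are then rotated onto the shared one by orthogonal Procrustes
(so the specific deviation from the shared frame is minimal, not an
arbitrary basis artifact), and the stacked
$[G_0; U^1; \dots; U^M]/\sqrt{M+1}$ is *exactly* orthonormal because
each block is. The effective per-band projection realizes the model's
$(1-\sigma)/\sigma$ mixing and has full column rank for every
$\sigma$.

**Second: a subtractive variance term is inert, and raw residual
ratios chase noise; reward variance in the denominator and shrink the
within scatter.** The obvious way to add a PCA-like reward — subtract
$\alpha\,\Theta$ (with $\Theta^m = Z^m (Z^m)^\top$) from the numerator —
is neutralized by the ratio's scale invariance: at the optimum the
shift $\rho^* H$ cancels $\alpha\,\Theta$ on exactly the directions
where $\Theta$ is proportional to $H$, which for residual scatters is
essentially all data directions, so the variance term never influences
the chosen subspace. The package therefore places the retained
variance in the *denominator*,
$\text{within} / (\text{between} + \alpha\,\Theta)$: there it survives
the ratio, keeps the objective bounded below by zero, and genuinely
rewards shared directions that carry data energy. Separately, a raw
within/between ratio is dominated in finite samples by "within-null"
mixture directions on which the own-class residuals nearly cancel
across samples while carrying no class structure — the ratio can be
made arbitrarily small by noise. The package applies the standard
regularized-discriminant remedy, shrinking every within scatter toward
a scaled identity, $W_w + \gamma_w \operatorname{mean}(\operatorname{diag}
W_w)\, I$, which is scale-free, and solves the *denominator-whitened*
form: the denominator scatter is eigendecomposed on its range, the
numerator is whitened there, and the trace-ratio iteration runs with an
identity denominator (where the trace-ratio and per-direction-ratio
solutions coincide), after which the basis is mapped back and
re-orthonormalized. With these two changes the shared component
reliably recovers the generating subspace on synthetic data (median
largest principal angle about 6° at the full latent rank) instead of
locking onto noise directions, without changing any of the exported
operation contracts — `solve_projection()`, `f_rho()` and
`stack_operators()` retain their documented behavior.

The dictionary step uses the quotient-rule gradient of the
within/between energy ratio at fixed codes and projections (the
variance term does not depend on $D$, so descent on the energy ratio is
descent on the full objective), followed by atom re-normalization and
backtracking halving of the step size; if no step size avoids an
increase the dictionary is left unchanged, so the objective is
non-increasing by construction.

## Parameters and defaults

* `alpha` (default 0.5): weight of the variance-retention reward on
  the shared component. 0 disables it, leaving a pure Fisher
  criterion.
* `sigma` (default `1 - alpha`): shared/specific mixing. The default
  couples the two knobs so a stronger shared-variance reward goes with
  a stronger shared component.
* `lambda_code` (default 0.01): ridge penalty of the coding step. The
  coder has the closed form $(\hat D^\top \hat D + \lambda I)^{-1}
  \hat D^\top \hat z$; an ISTA lasso coder (`ista_code()`) is provided
  as an alternative when sparse codes are wanted.
* `atoms_per_class` (default 15) and `p` (default
  $\lceil 0.9\,d \rceil$ once data are seen): dictionary and subspace
  sizes. The residual classifier solves least squares against each
  class's *projected* sub-dictionary, so `atoms_per_class` should stay
  below `p` — once a class's projected atoms span the whole subspace,
  every class reconstructs everything and residuals stop
  discriminating. The package's own benchmark uses `p = 10`,
  `atoms_per_class = 5` on 20-dimensional data.
* `lambda_rho` (default 0.5): damping of the trace-ratio Newton step;
  1 is the undamped exact step, smaller values trade speed for
  monotone approach.
* `eta` (default 0.01): initial dictionary step, halved up to 10 times
  by backtracking.
* `gamma_w` (default 1): within-scatter shrinkage intensity; 1 adds a
  ridge equal to the scatter's mean diagonal, which is scale-free.
  Setting it to 0 recovers the unshrunk ratio and exposes the
  within-null degeneracy discussed above.
* `max_iter` (default 50) and `tol` (default 1e-6): outer loop budget
  and relative objective-change stopping rule.

## The synthetic generator

`make_synthetic()` draws data from exactly the structure the model
assumes, so ground truth is available: a common mixing $B_0$ and
band-specific mixings $\tilde B^m$ with unit-norm columns,
effective mixings $B^m = (1-\sigma_{\text{true}}) B_0 +
\sigma_{\text{true}} \tilde B^m$, and per sample a nonnegative
coefficient vector supported on its class's block of `k_true` atoms
(entries $|N(0,1)| + 0.5$), observed through $B^m$ plus isotropic
Gaussian noise. Train and test sets are drawn i.i.d. from the same
truth. This enables three kinds of checks that real data cannot
provide: an oracle ceiling (`oracle_predict()` classifies by true
class-subspace residuals and is exact at zero noise), parameter
recovery (at $\sigma_{\text{true}} = 0$ the learned $G_0$ should span
the data's principal subspace — note the recovery target is only
well-defined at $p = C \cdot k_\text{true}$, the generator's full
latent rank, since below it the Fisher criterion may legitimately
prefer latent directions over raw-variance order), and controlled
degradation (accuracy must fall monotonically as `noise_sd` grows).

The standing benchmark `separable_preset()` — 3 bands, $d = 20$,
3 classes, 40 train and 40 test samples per class, `k_true` 4,
`sigma_true` 0.5, `noise_sd` 0.05 — is the package's own choice of a
problem size that is small enough to fit in seconds yet large enough
that the degeneracies described above actually bite when the
regularizers are removed.

## Feature extraction

For raw signals, `extract_multiband()` composes `slice_epochs()`
(non-overlapping fixed-length epochs), per-band power via
`welch_psd_features()` (Welch's method: Hann-windowed overlapping
segments, periodogram averaging, power integrated over the band with
one-sided spectrum scaling that preserves Parseval's identity to
within discretization error), and an optional log transform and
z-scoring. `default_bands()` supplies the conventional EEG ranges
(delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45 Hz);
`bandpass()` provides a Butterworth filter when time-domain band
signals are wanted instead of powers.

## Limitations

* The generator matches the model's own assumptions; benchmark
  accuracies are upper bounds on what mismatched real data would give,
  and say nothing about cross-subject generalization.
* The projection step solves the shared and specific components
  separately rather than jointly; this guarantees well-posedness and
  exact orthonormality but is a block-coordinate approximation to the
  joint problem, and the alternating loop as a whole carries no global
  convergence guarantee (only per-step monotonicity of the dictionary
  objective).
* Coding inside the projected subspace feeds back into the scatters
  that choose the projection; with `gamma_w = 0` this feedback can
  self-reinforce noise directions. The default shrinkage mitigates but
  does not formally eliminate it.
* Scatter solves are dense eigen-decompositions, $O(d^3)$ per band per
  iteration: fine for band-power features ($d$ in the tens to
  hundreds), not intended for raw high-dimensional signals.
* Classes are assumed balanced enough for the residual votes to be
  meaningful; no class weighting is implemented.
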