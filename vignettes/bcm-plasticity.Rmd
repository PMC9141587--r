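---
title: "BCM plasticity with lateral connections: model, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BCM plasticity with lateral connections: model, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcmnet)
```

## The model

`bcmnet` simulates rate-based synaptic plasticity in the
Bienenstock–Cooper–Munro (BCM) framework, in the Law–Cooper variant. A
layer of $N$ neurons receives a presynaptic pattern $x \in \mathbb{R}^d_{\ge 0}$
and responds

$$ z = \sigma\!\left( (I - L)^{-1} W x \right), $$

where $W$ is the $N \times d$ synaptic weight matrix, $\sigma$ an
elementwise activation (ReLU by default; linear and logistic are
available), and $L$ the lateral (cortico-cortical) coupling matrix with a
single interaction strength $\xi$ everywhere off the diagonal and zeros on
it (no self-interaction). Positive $\xi$ is cooperation, negative $\xi$
competition. The activation is applied *after* the lateral mixing, so with
$\xi = 0$ each neuron reduces to the classical single-neuron response
$z_i = \sigma(w_i \cdot x)$.

Each neuron carries a *modification threshold* $\theta_i$, a long-term
average of its squared activity. On every batch $b_t$,

$$ \theta_t = \gamma\,\theta_{t-1} + (1-\gamma)\,\langle z^2 \rangle_{b_t}, $$

with memory factor $\gamma \in [0,1]$, and the synapses move along the
Law–Cooper plasticity direction

$$ \frac{dw_{ij}}{dt} \;=\; \frac{z_i\,(z_i - \theta_i)\,x_j}{\theta_i}, $$

averaged over the batch. Activity above $\theta$ potentiates the active
synapses (LTP), activity below depresses them (LTD); the superlinearity of
$\theta$ in $z$ (squaring) is what turns selective states into attractors,
and the division by $\theta$ is what stabilises them. On $K$ orthogonal
patterns presented with probabilities $p_k$, the stable states of a single
neuron respond $1/p_k$ to exactly one pattern and $0$ to the rest — the
package's orthogonal fixture exists because this prediction is exact and
testable.

## Training

Training presents random batches (one parameter update per batch) and
steps the weights either by plain fixed-rate ascent
($W \leftarrow W + \eta\,\Delta W$) or with Adam. The BCM update is not
the gradient of any loss, so Adam is fed $g = -\Delta W$ and its standard
descent recursion then performs ascent along the plasticity direction;
under a constant direction the first Adam step has magnitude $\approx$
the learning rate. The batch aggregate of the update is the arithmetic
*mean* over batch elements, so learning rates are batch-size invariant.

Within one step the order is: forward pass, threshold update on the
current batch, plasticity update using the *new* $\theta_t$, optimizer
step. The threshold recursion indexes $\theta_t$ with the time-$t$ batch
average, and the weight update at step $t$ uses $\theta_t$, not
$\theta_{t-1}$.

Convergence is monitored on the epoch average
$\langle\theta\rangle = \frac{1}{B}\sum_{t=1}^{B}\theta_t$ ($B$ steps per
epoch), which smooths the often noisy per-step trace. A neuron counts as
converged when the relative change of $\langle\theta\rangle$ stays below
`rel_tol` (default 0.01) across a trailing window (default 10
epoch-to-epoch changes). This is deliberately conservative: with small
batches and $\gamma$ near 1 the epoch average still fluctuates by a few
percent, so runs often use the epoch cap instead; the cap, not the flag,
bounds run time.

## Key parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `xi` | 0 | dimensionless, $\xi \ne 1/(N-1), -1$ | lateral strength; sign selects cooperation vs competition |
| `gamma` | 0.9 | $[0,1]$ | threshold memory; values near 1 enforce high selectivity |
| `batch_size` | 20 | patterns | batch average entering $\langle z^2\rangle$ and the update |
| `learning_rate` | 0.001 (Adam) / 0.01 (plain) | per step | Adam reference defaults |
| `weight_scale` | 0.01 | activity units | initial weights small vs unit-scale inputs (below) |
| `theta_floor` | $10^{-8}$ | squared activity | division safety (below) |

## Numerical choices

* **Threshold floor.** The update divides by $\theta$, and at
  initialisation $\theta$ can be numerically zero (e.g. a ReLU neuron that
  is silent on its first batch). $\theta$ is clamped below at
  $\varepsilon_\theta = 10^{-8}$ rather than raising an error, so early
  training can escape nearly silent starts.
* **Threshold bootstrap.** $\theta_0$ is taken from the first batch's mean
  of $z^2$ (then clamped), not from an arbitrary constant; the first
  update therefore sees $\theta_1 = \langle z^2\rangle_{b_1}$ for any
  $\gamma$.
* **Weight initialisation.** Entries are i.i.d. Gaussian with standard
  deviation `weight_scale / sqrt(d)`. Under ReLU the *half-normal*
  (absolute value) variant is used by default: a zero-mean start leaves a
  ReLU neuron silent on all $K$ orthogonal patterns with probability
  $2^{-K}$, and a silent ReLU neuron has identically zero plasticity — it
  can never recover. The default scale (0.01) keeps initial weights small
  relative to unit-scale inputs so receptive fields are shaped by the
  data; large initial weights pin each neuron to its random initial
  pattern preference and mask the lateral-coupling effects the model is
  meant to exhibit.
* **Lateral mixing.** $(I-L)^{-1}$ is computed once per $\xi$ by a linear
  solve and cached ($L$ is constant during a run). $I - L$ has eigenvalues
  $1-(N-1)\xi$ and $1+\xi$; both are checked against a $10^{-8}$
  singularity tolerance and `build_lateral()` refuses both critical values
  ($\xi = 1/(N-1)$ and $\xi = -1$), naming them in the error.
* **Divergence guard.** If any weight exceeds $10^6$ in magnitude or goes
  non-finite, training aborts with an error naming the epoch — strong
  coupling is known to destabilise the dynamics, and continuing would only
  produce NaNs.
* **Selection-set ties.** A pattern exactly at the neuron's mean response
  is *not* selected (strict inequality), so a constant-response neuron has
  $\alpha = 0$; with non-uniform presentation probabilities the mean is
  probability-weighted.
* **Floating-point equivalence.** A decoupled ($\xi=0$) network trains
  identically to independent single-neuron runs sharing the same batch
  schedule; numerically this holds to $\sim 10^{-12}$ relative tolerance
  rather than bitwise, because BLAS kernels sum matrix products of
  different heights in different orders.

## Population metrics

For each neuron, the selection set
$A_i = \{x : z_i(x) - \mathrm{E}[z_i] > 0\}$ and selectivity
$\alpha_i = |A_i|$; for the population, the number of distinct selected
patterns $S$, the overlap index $\beta = S / \bar\alpha \in [1, N]$
($1$ = total overlap, $N$ = pairwise disjoint, maximal competitiveness),
and the memorization capacity $C = \sum_i \alpha_i$. Comparing the number
of training patterns $T$ to $C$ classifies the regime: redundant
($T \ll C$), critical ($T \approx C$), ill-posed ($T \gg C$); the
asymptotic symbols are operationalised as $T/C < 0.5$ and $T/C > 2$, and
$C = 0$ is ill-posed by convention. Selectivity experiments evaluate with
the lateral coupling turned off (independent neurons); competitiveness
($\beta$) experiments keep the trained coupling on. Both modes are
exposed via `competition_report(..., use_lateral =)`.

```{r metrics-demo}
ps <- clustered_patterns(seed = 42)
fit <- bcm_train(ps, n_neurons = 5, xi = -0.1, epochs = 150)
glance(competition_report(fit, ps))
```

## The synthetic generators

`orthogonal_patterns()` builds axis-aligned patterns whose BCM fixed
points are known in closed form; it is the fixture behind every
convergence and selectivity check. `clustered_patterns()` emulates the
*class structure* of image benchmarks: each class prototype occupies a
distinct contiguous block of $\lfloor d / n_{\text{classes}}\rfloor$
features with uniform$(0.5, 1)$ magnitudes, and patterns are noisy copies
(Gaussian noise, clipped at 0 to preserve the positivity of presynaptic
rates). Zero-noise patterns of different classes are therefore exactly
orthogonal, and weight bitmaps of trained neurons are directly
interpretable as class blocks.

What the generator does *not* emulate: within-class manifold structure
(styles of a handwritten digit), correlated pixels, overlapping class
supports, or heavy-tailed intensity distributions of natural images.
Passing tests on these fixtures demonstrate the plasticity mechanics —
fixed points, selectivity development, threshold dynamics, the
competitiveness trend under $\xi$ — not performance on real images. For
real data the package reads MNIST IDX and CIFAR-10 binary files
(`read_idx()`, `read_cifar10_batch()`, `preprocess_images()`), with
pixel intensities scaled to $[0,1]$ and flattened row-major,
channel-last; no files are downloaded, and no benchmark results are
claimed here.

With non-uniform presentation probabilities, an epoch is $n$ weighted
draws with replacement (split into batches) rather than a permutation;
this mode exists to exercise the $1/p$ fixed-point prediction, while the
uniform case keeps standard epoch semantics (every pattern exactly once
per epoch).

## Problem sizes used by the test suite

The checks run at desk scale: orthogonal fixtures with $K \in \{2,4,8\}$
patterns and a single neuron (up to a few thousand full-batch steps), and
the clustered fixture at its defaults (10 classes × 20 patterns,
64 features, noise sd 0.1) with 5 neurons, batch size 20 and a 300-epoch
cap for the lateral-strength sweep
$\xi \in \{+0.05, 0, -0.05, -0.1, -0.2\}$ over 5 batch-order seeds.
These sizes were chosen so that each scientific property is exercised
well inside its asymptotic regime while a full run of the suite stays in
the minutes range; the qualitative results (selective endpoints at $1/p$,
$\beta$ rising monotonically with inhibition, $\beta \to 1$ under weak
excitation) are stable across seeds at these sizes.

## Known limitations

* Uniform $\xi$ only: the coupling type admits no per-pair heterogeneity,
  by design.
* No alternative threshold laws (e.g. $\mathrm{E}[z]^2$): the squared
  form is the one with the convergence guarantee.
* Training is fully unsupervised; there is no supervised readout, no
  early stopping on task metrics, and no multi-layer stacking.
* The convergence flag is conservative under small batches and large
  $\gamma$; treat the epoch cap as the practical stopping rule there.
* Hyperparameters for full-scale image runs (hundreds of neurons,
  thousands of epochs) are not tuned here; the defaults are documented
  choices for the synthetic fixtures.
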