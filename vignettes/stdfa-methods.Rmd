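---
title: "Spike-train level direct feedback alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-train level direct feedback alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdfa)
```

## The problem

Training multi-layer spiking neural networks (SNNs) with backpropagation
requires feeding errors backwards through the *transpose* of the forward
weight matrices, layer by layer. That is biologically implausible (the
"weight transport" problem) and expensive in neuromorphic hardware, where it
costs wide multipliers and a backward latency that grows with network depth.
Direct feedback alignment (DFA) replaces the transported transposed weights
with *fixed random* feedback matrices that project the output-layer error
straight onto every hidden layer; the network learns to make those random
feedback directions useful. This package implements DFA at the
*spike-train level*: credit assignment operates on quantities accumulated
over a whole trial rather than step by step through time, which keeps the
backward pass small, local, and depth-independent.

## Neuron model

Neurons are discrete-time leaky integrate-and-fire (LIF) units with a
first-order synapse; time advances in unit steps, and the time constants
`tau_m` (membrane) and `tau_s` (synapse) are expressed in steps. The
membrane potential of neuron $i$ follows

$$\alpha_i[t] = (1 - 1/\tau_s)\,\alpha_i[t-1] + (1/\tau_s)\textstyle\sum_j w_{ij}\,s_j[t],
\qquad u_i[t] = (1 - 1/\tau_m)\,u_i[t-1] + \alpha_i[t],$$

with a spike emitted and $u_i$ reset to zero when $u_i \ge \nu$. Two
deliberate choices here:

* **The membrane integrates the current without a $1/\tau_m$ prefactor.**
  The online per-synapse trace recurrence (below) injects its synaptic trace
  into the membrane-side trace the same way, and with matching resets this
  makes $u_i[t] = \sum_j w_{ij} q_{i|j}[t]$ an exact identity of the
  simulator — the membrane potential *is* the weight-sum of per-synapse
  contributions, as the spike response model formulation requires. It also
  underwrites the count approximation $o_i \approx a_i/\nu$ used by the
  learning rule, where $a_i = \sum_j w_{ij} e_{i|j}$ is the total
  post-synaptic potential. In practice each firing consumes at least $\nu$
  with bounded overshoot, so $a_i/\nu \ge o_i$ with the two close in
  rate-driven regimes; the test suite measures this rather than asserting
  exactness.
* **Reset to zero, no refractory period, at most one spike per neuron per
  step.** PSP accumulation restarts at the last post-synaptic spike, which
  is exactly what the reset implements; a binary per-step firing decision
  matches fixed-step hardware.

Defaults are $\nu = 1$, $\tau_m = 16$, $\tau_s = 4$ — time constants are
powers of 2 so that the fixed-point datapath can realise every decay as an
arithmetic shift. All are configurable through `neuron_params()`.

The closed-form PSP kernel

$$\epsilon(s,t) = \frac{e^{-\max(t-s,0)/\tau_s}}{1-\tau_s/\tau_m}
\left[e^{-\min(s,t)/\tau_m} - e^{-\min(s,t)/\tau_s}\right] H(s)\,H(t)$$

is the continuous-time response at $t$ steps after a pre-synaptic spike for
a neuron whose accumulation window opened $s$ steps ago. It equals the
integral of the membrane leak against the synaptic impulse response
$e^{-x/\tau_s}/\tau_s$ over $[0, \min(s,t)]$; the test suite verifies the
closed form against numerical quadrature of that integral to well below
0.1%. The normalisation requires $\tau_m \neq \tau_s$, which
`neuron_params()` enforces as $\tau_m > \tau_s > 0$.

## Spike-train level post-synaptic potential (S-PSP)

The S-PSP $e_{i|j}$ aggregates the effect of pre-neuron $j$'s whole spike
train on post-neuron $i$, evaluated at $i$'s firing times:

$$e_{i|j} = \sum_{t_i^{(f)}} \sum_{t_j^{(f)}}
\epsilon\left(t_i^{(f)} - \hat t_i^{(f)},\, t_i^{(f)} - t_j^{(f)}\right).$$

Two implementations coexist, on purpose:

* `spsp_direct()` — the event-based double sum, the *specification*. In
  `"discrete"` mode the kernel is the closed-form geometric sum of the
  fixed-step recurrences, so it equals the online path in exact arithmetic;
  in `"continuous"` mode it uses the closed-form kernel above. It exists as
  a reference and test oracle, not a production path.
* `spsp_online_step()` / the compiled trial kernel — the production path.
  Per synapse, two traces advance each step:
  $p \leftarrow (1 - 1/\tau_s)p + (1/\tau_s)\,\mathrm{pre}$, then
  $q \leftarrow (1 - 1/\tau_m)q + p$, and when the post-neuron fires,
  $e \leftarrow e + q$ and $q \leftarrow 0$. Everything is accumulated
  during the forward pass; nothing about the spike history needs storing.

Resolved ambiguities, fixed as package contracts: within a step the order is
pre-spike injection → `p` update → `q` update → post-fire capture
(`e += q; q = 0`), so a pre and post spike in the same step contribute to
`e` in that step. Before the first post-synaptic spike the accumulation
window extends back to the trial start ($\hat t_i = -\infty$), consistent
with `q` accumulating from step one. The pre-spike injection carries a
$1/\tau_s$ gain — the normalised discrete form — with any discrepancy
against an unnormalised impulse convention absorbed into the weight scale.

The suite checks, over hundreds of random train pairs, that the online
accumulator and the event-based oracle agree to better than $10^{-9}$
relative error (observed: order $10^{-16}$, pure floating-point grouping
noise), that accumulation is monotone, additive over disjoint pre-trains,
and that the discrete value converges to the continuous kernel (first order
in $1/\tau_s$) as time constants and spike spacings scale up together.

## Learning rules

With firing-count targets $y$ (`target_counts()`: `hi` = 35 for the correct
class, `lo` = 5 otherwise, at the default 100-step horizon), the rate-coded
loss is $E = \tfrac12\lVert o - y\rVert^2$ and the output error is
$\delta^o_i = (o_i - y_i)/\nu$. Hidden errors come from one of:

* **ST-DFA** — $\delta^k = B^k\,\delta^o$ with $B^k$ fixed random
  (`make_feedback()`, `"real"` variant: uniform entries, RMS-matched to the
  power-of-2 set so learning rates transfer across variants).
* **ST-DFA-2** — $B^k$ entries drawn from $\{-4,-2,-1,0,1,2,4\}$ (0
  included, as a masked connection); every product is realised as a
  sign-corrected arithmetic shift. The shift path and the dense path
  accumulate in the same order and each shift product is exactly the
  corresponding multiplication, so they agree *bit for bit* — in floating
  point and on fixed-point raw integers. This is asserted, not approximated.
* **BP baseline** — symmetric-weight backpropagation in the same
  spike-train level form,
  $\delta^k_i = \frac1\nu \sum_l \delta^{k+1}_l w^{k+1}_{li}
  (e^{k+1}_{l|i}/o_i)$ with $0/0 \to 0$, the per-spike average S-PSP
  standing in for the exact S-PSP/count sensitivity (whose exact micro-level
  form this package does not attempt). Provided for comparison only.
* **frozen** — forward pass only; the no-learning control.

The update is $\Delta w_{ij} = \eta\,\delta_i\,e_{i|j}$, applied as
$w \leftarrow w - \Delta w$ (descent on $E$; the sign convention is fixed
here as a package contract). The output layer always trains on its own
$\delta^o$ directly — the derivation of the hidden rule reduces to exactly
that at the output. Updates are per-example (online): forward pass,
output error, then all hidden layers' errors computed concurrently from the
same $\delta^o$ — no hidden layer sees another's update, which is what
makes the backward phase depth-independent, and reordering hidden-layer
update computation provably changes nothing.

## Initialisation and learning rate

Neither the weight initialisation nor the learning rate is prescribed by
the algorithm, so the package fixes defaults and documents the reasoning:

* Hidden weights: uniform on $(-a, a)$, $a = 2.5/\sqrt{\text{fan-in}}$ —
  fluctuation-driven drive of order the threshold for input rates in the
  0.05–0.35/step range.
* Output weights: uniform on $(0, 0.66/\sqrt{\text{fan-in}})$, i.e.
  **positive**. This is deliberate and matters: the S-PSP of a neuron that
  never fires is identically zero, so a silent output neuron receives zero
  weight update under any spike-train level rule and can never re-activate —
  a degenerate fixed point. Zero-mean output initialisation leaves a
  substantial fraction of output units dead at the start and training then
  cannot balance the per-class counts; a positive readout initialisation
  keeps every output unit initially active, after which the count targets
  (`lo` > 0) keep them alive.
* Learning rate: default $\eta = 2\times10^{-5}$. Hidden errors are of
  order $\lVert\delta^o\rVert \cdot \lVert b\rVert \sim 10^2$ and S-PSPs of
  order $10^1$ at the default task scale, so this keeps single-example
  weight steps in the $10^{-2}$ range of the initial weight scale. Larger
  rates (above roughly $10^{-4}$) overshoot: output neurons are driven
  silent and die, exactly the degenerate fixed point described above.

## Fixed-point emulation

The quantised datapath mirrors a digital implementation whose storage
formats are: weights signed 17-bit with 12 fractional bits; S-PSPs unsigned
11-bit with 6 fractional bits; membrane potentials signed 9-bit with 3
fractional bits (`fp_defaults()`). Decisions the hardware leaves open,
fixed as configurable package contracts:

* Quantisation (`quantize()`) rounds to nearest, ties to even, and
  *saturates* rather than wrapping.
* Decays inside the datapath truncate: `x - (x >> k)` with an arithmetic
  (floor) shift, as shift-based hardware does (`shift_decay()`).
* The weighted-current inner product accumulates at full
  `frac(w) + frac(e)` precision and is re-quantised to the membrane format
  by a truncating shift — wide accumulator, narrow storage.
* Errors $\delta$ and updates $\Delta w$ follow the weight format; weights
  live on the weight lattice throughout quantised training.

The compiled fixed-point kernel works on raw integers only, so quantised
forward passes are bit-identical across runs and platforms; the suite also
checks it against an independent R integer step-through. Spike-count
divergence between float and quantised passes is measured (the
3-fractional-bit membrane is coarse) but learning survives it: quantised
ST-DFA-2 still reaches the learning criterion on the synthetic task. Note
the S-PSP storage saturates at $2^{11}-1$ raw ($= 32.0$), which clips the
largest S-PSPs relative to float mode; this is the hardware's tradeoff and
is reproduced faithfully.

## Synthetic task and what it shows

`make_rate_task()` generates the rate-coded classification problem used
throughout: `n_classes = 3` templates over `n_inputs = 20` input neurons
(template size 6, of which `round(0.2 * 6) = 1` neuron is shared between
all classes at the default `overlap = 0.2`); template neurons fire at
`peak_rate = 0.35` per step, background at `base_rate = 0.05`, for
`horizon = 100` steps, 20 examples per class. Rates were chosen once as a
realistic rate-coded contrast (roughly 7:1) with non-trivial background
noise; the generator exposes its ground-truth templates so tests can bound
achievable accuracy with a template-matching classifier independently of
any learner. Everything is a pure function of the spec (seed included).

This task emulates rate-coded, Poisson-sampled inputs with class structure
and label noise — the statistical skeleton of encoded image benchmarks. It
does **not** emulate their scale (hundreds of inputs, tens of thousands of
examples), temporal structure within a trial, or realistic class overlap
geometry; passing the learning tests shows the credit-assignment machinery
works, not that any particular benchmark accuracy would be reached. For
real image data the package provides the IDX container reader
(`read_idx()`), the 14×14 `center_crop()`, and `poisson_encode()`, but
ships no datasets and performs no downloads.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely from generated data
at sizes chosen to exercise every code path quickly: 200 random
spike-train pairs at $T = 100$ for oracle agreement; a 20×20 grid for the
kernel/quadrature comparison; 100 random instances for shift/dense
equivalence; and for the learning property a 20-30-3 network, 5 seeds per
rule, up to 200 epochs with early stopping once the criterion accuracy is
reached (typically 2–4 epochs suffice). A full run of the acceptance
script takes a few seconds on one CPU.

## Known limitations

* No axonal/synaptic delays, conductance synapses, refractoriness, or
  recurrence; simulation is fixed-step only (the event-based S-PSP exists
  only as an oracle).
* The BP baseline is a simplified comparison rule, not a reproduction of
  any exact published micro-level gradient.
* Mini-batching, momentum and adaptive optimisers are out of scope; updates
  are strictly per-example.
* The count approximation $o \approx a/\nu$ carries overshoot bias for
  coarse inputs; tests treat it as approximate by design.
* Dead-unit protection is by initialisation and target floors only; there
  is no homeostatic mechanism, so extreme learning rates can still silence
  a network irrecoverably.
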