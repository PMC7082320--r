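# stdfa — spike-train level direct feedback alignment for spiking neural networks

`stdfa` trains multi-layer leaky integrate-and-fire (LIF) spiking neural
networks with **spike-train level direct feedback alignment (ST-DFA)**: the
output-layer error is projected straight onto every hidden layer through
*fixed random* feedback matrices, instead of being backpropagated layer by
layer through transposed forward weights. This removes the weight-transport
requirement, lets all hidden layers update concurrently (backward cost
independent of depth), and — in the **ST-DFA-2** variant, where feedback
entries are drawn from the signed power-of-2 set `{-4, -2, -1, 0, 1, 2, 4}`
— turns every feedback multiplication into an arithmetic shift, the form
used by digital neuromorphic hardware. A fixed-point emulation layer
reproduces such hardware bit for bit (weights Q17.12 signed, S-PSPs Q11.6
unsigned, membrane potentials Q9.3 signed).

The package is aimed at researchers in neuromorphic learning who want a
small, fully deterministic, testable reference implementation of
spike-train level credit assignment.

## The model in brief

Discrete-time LIF neurons (unit step; `tau_m = 16`, `tau_s = 4`,
threshold `nu = 1` by default) drive a per-synapse **spike-train level
post-synaptic potential (S-PSP)**,

e_{i|j} = Σ_{t_i^f} Σ_{t_j^f} ε(t_i^f − t̂_i^f, t_i^f − t_j^f),

the total kernel contribution of pre-neuron *j*'s train to post-neuron *i*,
evaluated at *i*'s firing times. The S-PSP is accumulated *online* during
the forward pass by two per-synapse traces (`p`, `q`) updated with shifts
and adds — no spike history is stored. With rate-coded loss
E = ½‖o − y‖² over output firing counts, the updates are

- output layer: δ_i = (o_i − y_i)/ν,
- hidden layer k: δ^k = B^k δ^o with B^k fixed and random,
- everywhere: Δw_ij = η δ_i e_{i|j}, applied as w ← w − Δw.

An exact event-based S-PSP evaluation (`spsp_direct()`) ships alongside the
online accumulator purely as a reference oracle; the two agree to floating
point rounding, which the test suite asserts at 1e-9.

## Worked example

Train a 20-30-3 network with hardware-friendly ST-DFA-2 on the built-in
synthetic 3-class rate-coded task (20 Poisson inputs, 100 time steps,
template overlap 0.2):

```r
library(stdfa)

res <- run_experiment("stdfa2", rate_task_spec(),
                      cfg = train_config(epochs = 50, stop_accuracy = 100),
                      seed = 1)
res
#> <stdfa_experiment> rule 'stdfa2', seed 1: 3 epoch(s), train 100.0% (best 100.0%), test 100.0%
res$log
#>   epoch      loss  accuracy
#> 1     1 83.100000  88.33333
#> 2     2 19.508333  98.33333
#> 3     3  6.816667 100.00000
```

The per-epoch `loss` is the mean rate-coded loss ½‖o − y‖² over the 60
training examples (count targets: 35 for the correct class, 5 otherwise),
and `accuracy` is the percentage of examples whose output firing counts
already pick the right class (argmax, ties to the lowest index). Here the
loss drops 83 → 6.8 while training accuracy reaches 100% in 3 epochs;
`test_accuracy` is measured on freshly sampled examples from the same class
templates.

Compare rules on identical data and seed — including the symmetric-weight
backpropagation baseline (`bp`) and the frozen-weights control:

```r
cmp <- compare_rules(c("stdfa", "stdfa2", "bp", "frozen"),
                     cfg = train_config(epochs = 5), seed = 1)
cmp$table
#>    rule seed epochs_run final_train_accuracy best_train_accuracy test_accuracy
#>   stdfa    1          5            100.00000           100.00000     100.00000
#>  stdfa2    1          5            100.00000           100.00000     100.00000
#>      bp    1          5            100.00000           100.00000     100.00000
#>  frozen    1          5             33.33333            33.33333      33.33333
```

Random feedback learns as well as symmetric-weight backpropagation on this
task, while the frozen control sits at the 33.3% chance level.

Lower-level pieces are exported individually — e.g. the S-PSP of one
synapse both ways:

```r
p <- neuron_params()
pre  <- spike_train(c(2, 9),  100)
post <- spike_train(c(10, 30), 100)
spsp_direct(pre, post, p)      # event-based reference: 1.298797
spsp_online_run(pre, post, p)  # online accumulator:    1.298797
```

Quantised (fixed-point) training is one flag away:
`train_config(quantize = TRUE)` runs the whole pipeline on the hardware
formats, bit-reproducibly. A thin CLI wraps the same functions:

```sh
Rscript inst/cli/stdfa train --net 20-30-3 --rule stdfa2 --epochs 50 \
        --seed 1 --log train.csv --out ckpt.json
Rscript inst/cli/stdfa eval --checkpoint ckpt.json --seed 9
```

For real image data, `read_idx()` loads the standard IDX containers (no
downloads performed), `center_crop()` reduces 28×28 images to the central
14×14 pixels, and `poisson_encode()` converts intensities to spike trains.

## Methods

See the methods vignette (`vignettes/stdfa-methods.Rmd`) for the model
derivations, the resolved discretisation ambiguities, fixed-point rounding
conventions, initialisation/learning-rate rationale, and known limitations.
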