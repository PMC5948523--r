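---
title: "Evolving convolutional/recurrent topologies for sensor-based activity recognition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gennas)
```

This vignette explains what `gennas` computes, the assumptions behind each
stage, the tunable parameters and their defaults, what the synthetic data
generator does and does not emulate, and the design choices made where the
method leaves room. It states no empirical result that the test suite or
the acceptance script does not itself compute.

## 1. Problem setting

The input is a multichannel recording from a body-sensor network: a
timestep × channel table with a per-timestep activity label (a high-prevalence
*null* class marks unannotated time). Channels are role-tagged —
body-worn sensors, quaternion orientation coefficients, and
object/environment sensors — and only the body channels are used for
classification. The classifier's unit of prediction is a sliding window of
`w` timesteps taken every `wstep` timesteps; performance is summarized by
the class-support-weighted F1,

$$F_1 = 2\sum_c \frac{n_c}{N}\,
\frac{\mathrm{precision}_c \cdot \mathrm{recall}_c}
     {\mathrm{precision}_c + \mathrm{recall}_c},$$

which down-weights rare classes exactly by their prevalence. A class whose
precision and recall are both zero contributes 0 (the ratio is otherwise
undefined; this convention is asserted in the tests).

## 2. Preprocessing

The chain is fixed and order-matters:
**filter → interpolate → zero-fill → normalize → window.**

1. *Channel filter*: drop quaternion and object/environment channels; keep
   body channels and the label. A sensor-rich deployment of 248 data
   channels (113 body + 16 quaternion + 119 object/environment) therefore
   retains exactly 113 channels.
2. *Interpolation*: wireless dropouts leave runs of missing values per
   channel; interior runs are linearly interpolated between the nearest
   defined neighbours. Leading/trailing runs have no neighbour on one side
   and are then set to zero — zero-filling happens *after* interpolation
   because interpolation cannot estimate them.
3. *Normalization*: per channel, $\hat x_c = (x_c - \min(c)) / (\max(c) -
   \min(c))$ into $[0,1]$, avoiding saturation of the network input.
   Constant channels map to 0. Statistics are computed on the training
   split only; when applied to validation/test data, values are clipped to
   $[0,1]$. The split-stats rule is our choice (the procedure itself does
   not specify it); it prevents leakage from evaluation data into the
   scaling.
4. *Windowing*: half-open windows $[s, s+w)$ starting at $0, w_{step},
   2\,w_{step}, \dots$, giving $\lfloor (T-w)/w_{step} \rfloor + 1$ windows,
   shaped as an $N \times 1 \times w \times C$ tensor. The window label is
   the label of the window's **last** timestep (the dominant convention for
   this dataset family, and the one that makes labels well defined when
   committee members with different `w` are aligned by window end); a
   majority-label rule is available via `label_rule = "majority"`.

Splits are contiguous time blocks (default 60% train / 20% validation /
20% test) rather than shuffled windows: overlapping windows from adjacent
timesteps would otherwise leak across splits.

## 3. Genotype, grammar and decoding

A chromosome is a fixed-capacity vector of integer codons (defaults:
codon size 256, capacity 100). Decoding repeatedly expands the left-most
nonterminal of a BNF grammar; at a rule with $k>1$ alternatives the next
codon $c$ selects alternative $c \bmod k$. Three decisions here were
genuinely open:

* **No wrapping.** Codons are never reused; a derivation that exhausts the
  chromosome is *incomplete*, carries no phenotype, and scores fitness 0 —
  consistent with how unrunnable models are handled downstream. With the
  shipped grammar a complete derivation needs at most 16–44 codons, so
  capacity 100 makes incompleteness rare in practice.
* **Codons are consumed only at choice points** (rules with more than one
  alternative), maximizing the effective use of the chromosome. The
  alternative behaviour is available (`consume_single = TRUE`).
* **Left-most expansion order**, the standard choice.

The grammar is a plain text file users can replace. Terminal text is kept
verbatim, so the generated sentence *is* the key=value phenotype
description (`B=.. w=.. wstep=.. f=.. eta=.. ck1=.. ...`), which parses
back into a `topology_spec` — the sentence, the on-disk phenotype format
and the pretty-printed architecture are one and the same string. The
shipped default grammar spans batch size {25, 50, 100}, window size
{8, 16, 24, 32}, step {1, 2, 4}, 1–5 conv layers (kernels
{8…256}, sizes {2, 3, 4}, pooling {1, 2, 3}, linear/ReLU), 1–3 dense
layers (feedforward/LSTM/GRU, units {128…1024}, dropout {0, 0.25, 0.5},
none/L1/L2), six learning rules and rates {1e-3, 5e-4, 1e-4}. The exact
production set of the original system is not recoverable from the source
figure; this reconstruction covers every architecture reported in its
results tables. A `tiny` grammar with reduced domains ships for desk-scale
runs and the end-to-end tests.

## 4. Network builder and trainer

A phenotype materializes as: stacked 1-D convolutions along the time axis
(valid padding, stride 1, the $C$ channels as input depth; `ck` kernels of
length `cs`, optional max-pooling of size `cp`), then dense layers, then a
softmax over the classes, trained with categorical cross-entropy.

Conventions the phenotype alone does not pin down (all documented in
`?build_model`):

* a recurrent layer returns its full hidden sequence when followed by
  another recurrent layer, otherwise its last hidden state; a feed-forward
  layer flattens whatever it receives; a recurrent layer receiving a flat
  vector treats it as a length-1 sequence;
* the layer activation of an LSTM/GRU replaces the tanh of the candidate
  and cell-output transforms; gates stay sigmoid;
* L1/L2 regularization applies to input-kernel weights with coefficient
  $10^{-4}$ (the method names the norms but no coefficient);
* gradients are clipped to a global norm of 5 — ReLU recurrences can
  otherwise explode;
* initialization is Glorot-uniform with forget-gate biases at 1;
  optimizer hyperparameters beyond the learning rate use the customary
  defaults (momenta 0.9/0.999, $\rho$ 0.9/0.95, $\varepsilon = 10^{-7}$).

**Feasibility.** Two failure modes are converted into a typed
`gennas_infeasible` signal that fitness evaluation maps to 0: the time
axis shrinking below one step through convolutions/pooling, and a
configurable parameter-count ceiling (default $5 \times 10^6$) standing in
for out-of-memory failures of oversized dense layers.

**Proxy fitness.** Training every candidate to convergence is what makes
naive architecture search intractable; the search instead scores each
topology by 5 epochs, each on a *fresh* uniform 5% sample of the training
windows (sampled over windows, not raw timesteps), evaluated by weighted
F1 on the validation split. The estimate is noisy but cheap, and only
needs to rank topologies, not measure them.

## 5. The evolutionary loop

Defaults: population 50, at most 100 generations, stop after 30
generations without improvement of the best nominal fitness, tournament
size 3, crossover rate 0.7, mutation rate 0.015, elite size 1, hall of
fame 20. The loop is generational: the elite (chosen by *nominal* fitness)
passes unmodified; everyone else is produced by tournament selection on
*adjusted* fitness, single-point crossover with the cut forced inside
$[1, \min(\mathrm{used}_1, \mathrm{used}_2) - 1]$ — the codon region both
parents actually decoded, so crossover always has a phenotypic effect —
and per-codon replacement mutation. Parents that are not crossed pass
through and are still mutated.

Niching adjusts fitness by mean similarity to the rest of the population,
$f_a(i) = f_n(i)\,(1 - \sum_{j \ne i} \mathrm{sim}(i,j) / (|P|-1))$.
Similarity is 0 between individuals with different conv or dense layer
counts, else the fraction of matching positionally-aligned hyperparameter
slots (3 input + 4 per conv layer + 5 per dense layer + 2 learning slots).
We interpret the slot set at the phenotype level rather than the codon
level because the gating condition keys on layer counts, which are
phenotype properties.

Further choices: tournament sampling is with replacement; all
tie-breaking (tournaments, elite ranking) is by uniform random draw from
the seeded stream, never by list order; fitness is memoized by phenotype
text across the run (the proxy is stochastic, so memoization freezes the
first draw — `memoize = FALSE` restores re-evaluation); the hall of fame
deduplicates by phenotype identity and keeps the highest fitness seen for
a phenotype. A single-elite population under memoization makes the best
nominal fitness non-decreasing across generations, which the tests assert.

## 6. Committees

The hall-of-fame topologies are retrained for 30 epochs on the full
training set and combined into incremental committees: committee $k$ is
the top-$k$ archive prefix, predicting per window by majority vote with a
deterministic tie-break chain — modal label, then largest summed
probability among tied classes, then lowest class index. Members may
differ in batch size (a training-only property) but must vote on aligned
windows: when window setups differ, windows are re-extracted per model and
aligned by end timestep, keeping only instants where every member has a
window ending. Label voting (not probability averaging) is the primary
rule; the summed probabilities enter only on ties. Row-normalized
confusion matrices are reported for the best committee.

## 7. Synthetic data: what it does and does not establish

The generator emulates the *shape* of body-sensor recordings: a
piecewise-constant label sequence of activity bouts separated by null
stretches (Poisson lengths, mean 60, minimum 20 timesteps, activity
classes drawn from reshuffled cycles so every class occurs); per-class,
per-body-channel signatures of offset plus sinusoid (amplitudes 0.5–1.5,
frequencies 0.02–0.2 cycles/timestep) behind a per-channel scale and
baseline, plus white noise (SD 0.1 by default); label-independent
quaternion/object channels; and missing values in geometric runs (mean
length 10) emulating wireless dropouts, not i.i.d. holes. Sinusoidal
signatures make temporal context informative, so recurrent layers are
genuinely exercised. Where no value was externally fixed, the defaults
above were chosen once as plausible for limb-worn accelerometry and are
not tuned against test outcomes.

What it deliberately does **not** emulate: biomechanics, inter-subject
variability, mixed sampling rates, label noise, or class confusability
structure. A green end-to-end test therefore establishes that the
search optimizes what it claims and that the pipeline is wired correctly —
not that the package reproduces published benchmark scores, which require
the real dataset and GPU-scale training and are out of scope.

## 8. Numerical notes and limitations

* Backpropagation (including through time) is verified against central
  finite differences to ~1e-6 relative error away from ReLU kinks.
* The niching adjustment is verified against a direct evaluation of its
  formula to 1e-12; the weighted F1 against an independent
  contingency-table implementation to 1e-12.
* Determinism: every stochastic stage derives its seed from one global
  seed (`derive_seed`); equal seeds give byte-identical artifacts on equal
  thread settings.
* At desk scale the 5-epoch/5%-sample proxy sees very few minibatches, so
  its *absolute* level is far below what full training reaches (the test
  suite asserts an above-chance floor at the protocol setting and a high
  floor once sampling covers half of a small set). On the full-size
  datasets the protocol was designed for, 5% is still tens of thousands of
  windows.
* The native trainer is single-threaded R matrix algebra: adequate for the
  reduced-domain grammar and desk-scale data, two to three orders of
  magnitude slower than a GPU backend for the full-size search space
  (512–1024-unit recurrent layers over 113 channels).
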