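# gennas — grammatical evolution of conv/recurrent networks for sensor-based activity recognition

`gennas` is an R implementation of neuroevolutionary architecture search
for human activity recognition from body-worn sensor recordings. Instead of
hand-designing a deep network for a given sensor deployment, the package
evolves the topology: a chromosome of integer *codons* is mapped through a
BNF grammar to a full network description — input window setup, 1–5
convolutional layers, 1–3 dense (feed-forward/LSTM/GRU) layers, learning
rule and rate — which is trained briefly and scored, and the best designs
are retrained in full and combined into majority-voting committees.

It is aimed at researchers working with OPPORTUNITY-style recordings
(whitespace-separated tables, one row per timestep, role-tagged channels,
missing values from dropped wireless sensors), but every stage also runs on
the built-in synthetic generator, so the whole system is testable offline.

## The method

**Genotype → phenotype.** A chromosome is a fixed-capacity vector of
integers in `[0, 256)` (defaults: capacity 100). Decoding repeatedly
expands the left-most nonterminal of a BNF grammar; a rule with *k* > 1
alternatives consumes the next codon *c* and picks alternative
`c mod k`. There is no codon wrapping: a derivation that exhausts its
chromosome is incomplete and scores fitness 0.

**Fitness.** A decoded topology is built and trained for 5 epochs, each on
a fresh uniform 5% sample of the training windows, and scored by the
class-support-weighted F1 on a validation split:

    F1 = 2 * sum_c (n_c / N) * (precision_c * recall_c) / (precision_c + recall_c)

**Niching.** To preserve diversity (and make committees worthwhile),
selection uses an adjusted fitness

    fa(i) = fn(i) * (1 - sum_{j != i} sim(i, j) / (|P| - 1))

where `sim` is 0 for individuals with different conv/dense layer counts
and otherwise the fraction of identical positionally-aligned
hyperparameter slots. Elites are chosen by nominal fitness `fn`.

**Operators.** Tournament selection (size 3), single-point crossover
(rate 0.7) forced inside the effectively-used codon region, per-codon
integer-replacement mutation (rate 0.015) applied to everything but the
elite, generational replacement, stall-based stopping (30 generations).

**Hall of fame and committees.** The best 20 distinct phenotypes seen
anywhere in the run are archived, retrained for 30 epochs on the full
training set, and combined into incremental majority-voting committees
(ties: largest summed probability, then lowest class index). Members with
different window setups vote on windows re-extracted per model and aligned
by end timestep.

The trainer is native R: 1-D convolutions along the time axis (valid
padding, stride 1, channels as depth), max-pooling, feed-forward/LSTM/GRU
layers, softmax with cross-entropy, and six learning rules (SGD, AdaGrad,
AdaDelta, RMSProp, Adam, Adamax), with gradients verified against finite
differences in the test suite.

## Worked example

```r
library(gennas)

# 1. synthesize a 12-channel recording (8 body + 2 quaternion + 2 object
#    channels, 3 classes incl. null) and write it in the on-disk dialect
cmd_synth("demo", synth_config(n_classes = 3, n_body = 8, n_quaternion = 2,
                               n_object = 2, T = 6000, seed = 42), seed = 42)
#> wrote 6000 timesteps x 12 channels (3 classes) to demo

# 2. evolve topologies (small population, reduced-domain grammar)
run <- cmd_evolve("demo/data.dat", "demo/schema.tsv", "demo/run",
                  evo = ge_config(population_size = 8, max_generations = 5,
                                  stall_generations = 5),
                  opts = run_config(seed = 42),
                  grammar_path = default_grammar_path("tiny"))
#> evolution: 5 generations, best fn 0.8937, hall of fame 10

# 3. fully train every hall-of-fame topology, then build committees
models <- cmd_train_hof("demo/data.dat", "demo/schema.tsv",
                        "demo/run/hall_of_fame.tsv", "demo/models",
                        opts = run_config(seed = 42))
#> trained 10/10 hall-of-fame models
cmd_ensemble("demo/models", "demo/data.dat", "demo/schema.tsv",
             "demo/committee", opts = run_config(seed = 42))
#> best committee: k=5, F1=0.9966
```

`demo/run/history.tsv` holds the per-generation best/mean fitness,
`demo/models/hof_f1.tsv` the proxy fitness next to the full-training F1 of
each archived topology (best entry: proxy `fn = 0.8937`, full-training
F1 = 0.9949 on the held-out test block), and `demo/committee/committee.tsv`
the incremental committee curve. The numbers above are what the code
prints for seed 42: the proxy estimate ranks topologies, full training
closes the gap, and the committee edges past the best single model.

The same stages are scriptable from the shell, e.g.

```sh
Rscript -e 'gennas::gennas_main()' synth --out demo --seed 42
Rscript -e 'gennas::gennas_main()' evolve --data demo/data.dat \
    --schema demo/schema.tsv --out demo/run --pop 8 --gens 5
```

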