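Package: gennas
Title: Grammatical Evolution of Convolutional and Recurrent Networks for
    Sensor-Based Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Neuroevolutionary architecture search for windowed multichannel
    sensor time series. Integer-codon chromosomes are mapped through a
    user-editable BNF grammar to convolutional/recurrent network topologies,
    which are scored by proxy training (few epochs on a small sample) and
    evolved with tournament selection, effective single-point crossover,
    integer-flipping mutation, elitism and similarity-based fitness sharing
    (niching). The best archive ("hall of fame") is retrained in full and
    combined into majority-voting committees. Includes the full preprocessing
    chain for body-worn sensor recordings (channel-role filtering, linear
    interpolation of missing runs, min-max normalization, overlapping sliding
    windows), a native minibatch trainer for 1-D convolutional, feed-forward,
    LSTM and GRU layers with six learning rules, weighted F1 scoring, and a
    synthetic-data generator emulating body-sensor recordings so the whole
    system is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
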