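Package: silentwm
Title: Activity-Silent Working Memory: Attractor Network Simulation and
    Behavioral/Neural Decoding Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying conscious and non-conscious ("activity-silent")
    working memory. Implements a one-dimensional continuous attractor neural
    network with short-term synaptic facilitation and depression, the
    target/mask/recall simulation protocol with regime classification,
    population-vector readout and critical-mask-amplitude search; a mixture
    model decomposing delayed-response error histograms into uniform guessing
    and a concentrated true-memory distribution (guess rate and precision);
    circular-linear correlation maps with a label-shuffling permutation null;
    temporal-generalization decoding of categorical and circular labels with
    stratified cross-validation, ANOVA feature selection and linear max-margin
    decoders; and seeded synthetic-data generators for behavioral trial tables
    and sensor-level epoch arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
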