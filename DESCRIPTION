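Package: psweep
Title: Parameter-Space Sampling, Derivation and Exploration for Computer Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless framework for parameter-space analysis of computer
    models: declare a model's control parameters in a manifest, draw uniform
    random parameter combinations, execute the model for each combination
    into a standard on-disk runs directory with stop/resume, summarize each
    run's raw output into derived columns of the runs table (aggregates,
    class-label statistics, ground-truth confusion counts, dimensionality
    reductions, first-row pass-through), and analyze the collection of runs
    with composable filters, histograms, Pareto-frontier and ROC analysis,
    normalized quality aggregation and static reports. Ships three fully
    seeded demo studies: clustering of a binary feature table with five
    internal validity indices, a parameterized differential-expression
    caller benchmarked on a synthetic spike-in RNA-seq count table, and a
    small multilayer-perceptron hyperparameter sweep over four classic 2-D
    classification datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    cluster,
    kernlab,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
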