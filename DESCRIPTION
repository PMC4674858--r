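Package: TFKOverlap
Title: Overlap Between Transcription-Factor Binding Targets and Knockout
    Effects, and Its Modulation by Functional Redundancy
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying how much of a transcription-factor (TF)
    binding dataset overlaps with a TF knockout-effect dataset in yeast-style
    regulatory data. Provides thresholding of TF-gene interaction tables into
    significant-set maps, Jaccard-based functional similarity and functional
    redundancy scores from annotation term sets, pooled overlap-percentage
    statistics over TF or gene sets with one-sided two-sample proportion
    tests, a generic stratified comparison pipeline over numeric and
    categorical TF/gene properties, and a seeded synthetic-data generator
    whose masking mechanism (a functionally redundant partner TF compensating
    for a knocked-out TF) makes every analysis stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Software, SystemsBiology, Transcription, NetworkInference
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
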