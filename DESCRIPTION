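Package: chromtrap
Title: Quantitative Analysis of Single Bacterial Chromosomes in Semi-Open
    Microfluidic Compartments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing semi-open microfluidic compartments by their
    diffusion lifetime and for analysing fluorescence time-lapse data of single
    cell-free bacterial chromosomes inside them. Implements the analytic
    compartment-lifetime model, single-molecule spot detection with sub-pixel
    localization, greedy track linking, mean-squared-displacement diffusion
    estimation, spatiotemporal clustering of surface-capture events into
    protein-synthesis arrivals, exponential arrival-time and dissociation-decay
    fitting with immobile fractions, electric-field stretch/relax kinetics,
    classical nucleoid segmentation with area time series, DNA-blob/condensin
    colocalization, and crowding dose-response aggregation. A fully
    ground-truth-known synthetic microscopy scene generator (Brownian tracks,
    Poisson surface arrivals with photobleaching, EM-CCD image formation,
    multi-blob nucleoid scenes, stretch kymographs) makes every stage testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
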