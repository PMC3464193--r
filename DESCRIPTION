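Package: gridsom
Title: Self-Organizing Map Model of Entorhinal Grid-Cell Scale Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates how medial entorhinal grid cells can learn hexagonal
    firing fields and a dorsoventral gradient of spatial scales from
    stripe-cell path-integration inputs. Category cells obey shunting
    on-center off-surround dynamics with habituatively gated self-excitation
    and competitive instar learning; a gradient of cell response rates (or
    habituation rates) selects the learned grid scale. Includes trajectory
    handling and a synthetic-trajectory generator, stripe-cell banks with
    cross-scale normalization and its ablations, the current-injection
    membrane-potential-oscillation paradigm with FFT frequency estimation,
    the full grid-cell metrics suite (rate maps, spatial autocorrelogram,
    gridness, spacing, orientation, field width, inter-trial stability), and
    a declarative runner for the model's simulation cases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
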