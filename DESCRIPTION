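Package: pdcsim
Title: Stochastic Modelling of Plasmacytoid Dendritic Cell Interferon
    Responses in Droplet Microenvironments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for single-cell analysis of
    interferon-alpha (IFNa) production by plasmacytoid dendritic cells
    (pDCs) in droplet microfluidic experiments. Provides Poisson
    encapsulation statistics for monodisperse droplets (occupancy,
    single-cell purity, calibration); a stochastic multi-state activation
    model (pDC0 -> pDC1 -> pDC2 -> death) with TLR-triggered rate
    amplification and paracrine type-I-interferon priming, simulated in
    droplets and in well-mixed bulk culture; two co-encapsulation
    interaction models (random-pair and early-responder) compared by a
    repeated train/test root-mean-square-error procedure; and UMI-based
    count processing (collision correction, down-sampling normalization,
    minimum-transcript cell filtering). Seeded synthetic-data generators
    make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
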