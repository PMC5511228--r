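Package: islandflora
Title: Long-Term Floristic Change Analysis for Island Archipelagos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying long-term change in archipelago floras
    from presence/absence occurrence records spanning two census periods.
    Fits Arrhenius power-law island species-area relationships by nonlinear
    least squares, partitions pairwise beta diversity into similarity,
    richness difference and replacement (the SDR simplex), computes NODF
    nestedness with cell-probabilistic (CE) null models and standardized
    effect sizes, and derives richness and compositional change statistics
    (Jaccard similarity between periods, G-tests of composition,
    inter-period regressions, per-island relative change). Includes a
    synthetic archipelago generator with controllable species-area scaling,
    nestedness and inter-period turnover for validating every stage of the
    analysis without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
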