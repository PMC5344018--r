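Package: renschkit
Title: Phylogenetic Analysis of Sexual Size Dimorphism and Rensch's Rule
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative phylogenetic tools for studying the evolution of
    sexual size dimorphism (SSD) and Rensch's rule in species-rich clades.
    Provides maximum-likelihood Brownian-motion ancestral state
    reconstruction, phylogenetic independent contrasts with reduced major
    axis (type II) allometric regression, Blomberg's K phylogenetic signal
    with permutation tests, per-branch ancestor-descendant change metrics
    (arithmetic change and rates in darwins) with qualitative coding and
    cross-tabulation, Fitch parsimony reconstruction of binary secondary
    sexual characters, and box-counting (Minkowski) fractal dimension of
    binary genital outline images. Includes simulators for Yule trees,
    correlated bivariate sex-specific Brownian trait evolution, binary
    character histories, and fractal raster phantoms, so every analysis can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    stats,
    utils,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    phytools,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
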