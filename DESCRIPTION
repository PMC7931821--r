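Package: mbgan
Title: Microbiome Abundance Simulation with a Wasserstein GAN and
    Copula Baselines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a Wasserstein generative adversarial network with
    gradient penalty (WGAN-GP) on a table of microbiome relative
    abundances and simulates synthetic samples that preserve first-order
    (sparsity, alpha/beta-diversity) and second-order (taxa-taxa
    correlation and proportionality) structure of the training data.
    The critic operates on a weighted phylogeny transformation of the
    composition: species abundances are aggregated over every node of a
    rooted taxonomic tree and amplified with a logarithmic map so that
    rare taxa contribute to the training signal.  Includes a
    Normal-to-Anything (NorTA) baseline with zero-inflated
    negative-binomial marginals, a seeded generator of ground-truth
    compositional fixtures, and a fidelity-evaluation suite (sparsity,
    Shannon diversity, unweighted UniFrac with non-metric
    multidimensional scaling, Spearman correlation structure, centred
    log-ratio transform and Lovell proportionality).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
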