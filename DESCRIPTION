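Package: acmolgen
Title: Attribute-Conditional Molecular Generation with a Latent-Space
    Auxiliary-Classifier GAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conditional inverse design of small molecules inside chosen
    intervals of logP, QED or synthetic accessibility.  An
    auxiliary-classifier generative adversarial network operates on
    length-250 molecular latent vectors behind a pluggable
    molecule-latent codec (a deterministic fingerprint-PCA surrogate is
    included), trained with adjusted adversarial losses, a Euclidean
    anchor on ground-truth latents, and an adaptive balance factor that
    reallocates update steps between generator and discriminator.  Ships
    the standard generation-quality metric suite (validity, novelty,
    uniqueness, internal diversity, nearest-neighbour similarity, BRICS
    fragment and Bemis-Murcko scaffold similarity, Frechet activation
    distance) and seeded synthetic fixtures.  Molecule parsing,
    descriptors and fingerprints are delegated to RDKit through a batch
    Python subprocess.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: Python (>= 3.8) with RDKit (the interpreter is looked
    up as 'python' on the PATH, or via options(acmolgen.python=) or the
    ACMOLGEN_PYTHON environment variable)
Config/testthat/edition: 3
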