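Package: idpae
Title: Generative Autoencoder Sampling of Disordered Protein Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines the conformational space of intrinsically disordered
    proteins (IDPs) with a generative autoencoder. A mirrored dense
    autoencoder compresses heavy-atom Cartesian coordinates of an
    ensemble (for example, the initial portion of a molecular dynamics
    trajectory) into a low-dimensional latent space; the training latent
    vectors are modelled by a multivariate Gaussian, from which new
    vectors are sampled and decoded into full conformations. Includes
    multi-model PDB input/output, Kabsch superposition and RMSD kernels,
    ensemble coverage metrics (reconstruction RMSD, best-match RMSD,
    pairwise diversity), latent-space histogram and Kullback-Leibler
    diagnostics, bond/angle geometry auditing, and a seeded multi-basin
    polymer trajectory simulator for testing.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
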