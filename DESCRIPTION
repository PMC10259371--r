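Package: manifoldlab
Title: Ground-Truth Laboratory for Manifold Embeddings of Conformational
    State Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic conformational continua -- latent grids of
    equispaced states, rigid multi-body hinge-rotation ensembles of a toy
    two-arm molecule, 3D electron-density maps rasterized from atoms as
    Gaussians, and 2D projection images with optional CTF and noise -- and
    embeds each datatype with diffusion maps and PCA.  Provides tools to
    analyze the spectral geometry of the embeddings against the analytic
    Laplace-Beltrami eigenfunctions of rectangular domains: cosine and
    Legendre mode assignment, detection of degenerate or misaligned
    eigenvector pairs and recovery of their rotation angles, Lissajous and
    Chebyshev subspace classification, and parabolic-harmonic multiplicity
    counting.  Includes seeded, end-to-end experiment recipes and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
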