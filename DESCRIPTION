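Package: contactmodes
Title: Contact-Based Conformational Dynamics of Membrane-Embedded Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of molecular-dynamics ensembles of membrane-embedded
    peptides through residue-residue contact degrees of freedom: per-frame
    binary contact matrices under an any-atom distance cutoff, dynamic-contact
    selection by mean contact frequency, principal component analysis of the
    contact covariance matrix, and Fisher linear discriminant analysis of
    truncated PC scores with back-mapping of discriminant loadings to signed
    residue-residue contact displacement maps. Also provides the conventional
    membrane trajectory analytics that accompany such studies (superposition
    RMSD, radius of gyration, protein-bilayer center-of-mass displacement,
    hydrogen-bond counting, periodic-boundary-aware membrane crossing
    counting, and lipid radial number density), plus seed-deterministic
    synthetic ensemble generators with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
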