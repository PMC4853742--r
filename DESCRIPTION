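Package: ionseqsim
Title: Hard-Sphere Simulation of Transverse Ionic Currents for
    Nanochannel Protein Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates identification of single amino acids by the ionic
    current they block in a pair of crossed nanochannels. Builds van der
    Waals surface geometry for the 20 proteinogenic residues, synthesizes
    proximal radial distribution functions (pRDFs) of K+ and Cl- around
    each residue, solves a hard-sphere area-balance equation for
    per-ion-species effective radii, samples transverse ionic current
    distributions by Monte Carlo over azimuthal and backbone dihedral
    conformations, and quantifies sequencing error with a
    maximum-likelihood classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
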