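Package: neutronRBE
Title: Energy-Dependent Neutron Relative Biological Effectiveness from
    Microdosimetric Spectra and DNA Damage Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the energy dependence of neutron relative biological
    effectiveness (RBE) for a soft-tissue phantom immersed in an isotropic
    monoenergetic neutron field.  Provides containers and moment arithmetic
    for lineal-energy spectra (frequency and dose distributions, dose-mean
    lineal energy, Kellerer saturation correction), a two-number-per-species
    condensation of the neutron-induced mixed secondary charged-particle
    field (dose fractions and dose-mean lineal energies), analytic DNA
    damage-versus-LET models with weighted fitting, genomic scoring of DNA
    double-strand-break clusters and short fragments, a coupling operator
    that converts a field composition plus damage curves into neutron-induced
    damage yields, two RBE models (saturation-corrected lineal energy ratio
    and DSB-cluster yield ratio), embedded regulatory reference curves
    (ICRP Publication 103 neutron weighting factor, U.S. NRC quality factor),
    and seeded synthetic generators that emulate the statistical structure of
    transport and track-structure Monte Carlo outputs so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    pracma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
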