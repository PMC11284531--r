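Package: radscav
Title: Radical Scavenging Kinetics from Quantum Thermochemistry
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assessment of antioxidant radical-scavenging activity from
    species-level thermochemistry, following the quantum-mechanics-based
    overall radical scavenging activity (QM-ORSA) protocol. Computes bond
    dissociation enthalpies, proton affinities and ionization energies of
    phenolic O-H/C-H sites, reaction free energies of the formal hydrogen
    transfer (FHT), proton transfer and single electron transfer (SET)
    mechanisms, acid-base speciation at physiological pH, transition-state
    theory rate constants with Eckart or Wigner tunneling corrections,
    Marcus-theory SET barriers, Collins-Kimball diffusion-corrected apparent
    rate constants, and population-weighted overall rate constants with
    branching ratios. Ships the published descriptor and kinetic tables for
    the coumarinolignans cleomiscosin A, B and C as a regression fixture,
    and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
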