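Package: pppgap
Title: Pariser-Parr-Pople Singlet-Triplet Gaps and Inverted-Gap Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiempirical pi-electron (Pariser-Parr-Pople) electronic
    structure for conjugated organic molecules, aimed at ultrafast virtual
    screening for inverted singlet-triplet gaps (INVEST).  Implements
    zero-differential-overlap self-consistent field theory with
    valence-state parameterization, configuration interaction singles,
    a perturbative dynamic-spin-polarization correction to the S1/T1 gap
    at both the SCF and CIS references, dipole-length oscillator
    strengths, geometry-based pi-system perception from XYZ/SDF input,
    and batch screening with regression and classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
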