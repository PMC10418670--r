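Package: xs1m5ni
Title: Self-Consistent Electron-Scattering Cross-Sections and Track
    Structure for 1-Methyl-5-Nitroimidazole
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Channel-resolved integral electron-scattering cross-sections
    for the candidate molecular radiosensitizer 1-methyl-5-nitroimidazole
    (1M5NI) over 0.1-1000 eV, packaged as a validated, interpolable library
    together with the tools used to assemble them: missing-angle correction
    of transmission-measured total cross-sections, resonance extraction of
    the electron-attachment channel from low-energy elastic curves,
    threshold-constrained partition of the inelastic residual into
    vibrational and electronic excitation, a semiempirical double
    differential inelastic model, first-Born rigid-rotor dipole rotational
    excitation, dissociative-attachment and cation fragmentation samplers,
    and an event-by-event Monte Carlo electron track-structure simulator
    driven by the data set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
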