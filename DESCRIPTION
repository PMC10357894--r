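Package: esrwpt
Title: Simulation-Independent Analysis of cw ESR Spectra by Wavelet Packet Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the simulation-free analysis of field-swept
    continuous-wave electron spin resonance (cw ESR) spectra. A spectrum is
    decomposed into a binary tree of approximation and detail components by an
    orthogonal wavelet packet transform (Daubechies-6, Daubechies-9 or
    Coiflet-3 filters), the structure-bearing detail component at the optimal
    decomposition level is selected, and hyperfine and superhyperfine
    multiplets are recovered as runs of evenly spaced peaks, even from poorly
    resolved or unresolved spectra. From the recovered multiplets the package
    computes hyperfine coupling constants (A, in gauss), the number of coupled
    nuclei, Cu(II) quartet parameters and g values, and identifies minor
    components in multi-component spectra by their distinct line spacings. A
    seeded first-order spectral simulator with known ground truth, spectrum
    readers and writers for plain-text formats, and a command-line interface
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
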