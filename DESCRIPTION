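Package: apEEG
Title: Modelling Action-Potential Contributions to Scalp EEG Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how neuronal action potentials (APs)
    shape scalp EEG power spectra. The package extracts unitary AP dipole
    responses from paired active/passive simulations by spike-triggered
    averaging, fits a linear spectral model whose scaling factor estimates
    the firing rate, assembles ensemble AP-generated EEG (apEEG) spectra
    under distance- and jitter-parameterized spike-synchrony models using
    exact double sums or Monte Carlo pair-term integration with Chebyshev
    stopping, computes cortical pair-distance densities and analytic
    surrogate lead fields, scores dendritic arbours with a volume-weighted
    asymmetry index, fits the aperiodic spectral trend with a
    double-Lorentzian synaptic-timescale model including noise-floor
    correction, and compares divisive, subtractive and mixed detrending
    strategies. A synthetic-data module generates every input the analysis
    expects: band-pass unitary AP kernels, excitatory/inhibitory
    populations, correlated spike-train pairs, cone-segment morphologies
    and trend-shaped EEG spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectra.R'
    'synchrony.R'
    'trend.R'
    'morphometry.R'
    'geometry.R'
    'synthetic.R'
    'unitary.R'
    'ensemble.R'
    'io.R'
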