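Package: pupaECG
Title: Electrode-Interface Circuit Models and ECG Analysis for Drosophila Pupae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-channel electrocardiogram (ECG)
    recordings of Drosophila pupae made with invasive tungsten needle,
    gelled, or liquid-metal (eutectic gallium-indium, GaIn) electrodes.
    Provides lumped RC equivalent-circuit models of the three
    electrode-tissue interfaces, Nernst interface potentials, Laplace-domain
    transfer functions with Bode analysis and bilinear-transform time-domain
    simulation, a synthetic pupal ECG generator with phenotype presets and
    realistic contamination (powerline, white noise, baseline wander,
    amplitude/period drift), the standard preprocessing chain (60 Hz IIR
    notch, moving-average smoothing), beat detection and period statistics,
    long-recording stability analysis, waveform feature extraction
    (positive duration, depolarization and repolarization slopes), and
    least-squares fitting of the first-order relative transfer function
    between paired invasive and noninvasive recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'rational.R'
    'AllClasses.R'
    'AllGenerics.R'
    'trace-methods.R'
    'synthetic.R'
    'electrodes.R'
    'transfer.R'
    'signal-processing.R'
    'beats.R'
    'features.R'
    'io.R'
    'pipeline.R'
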