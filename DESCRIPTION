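Package: autonomiq
Title: Autonomic Function Indices from Continuous ECG and Arterial Pressure Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-gated analysis of continuous electrocardiogram (ECG) and
    arterial blood pressure (ABP) waveforms for characterizing early autonomic
    dysfunction in critical care. Provides signal-quality assessment of hour-long
    segments (structural-similarity image classification of multi-lead ECG,
    consensus/spectral/kurtosis signal quality indices for lead selection, and a
    singular-value-decomposition subspace model for ABP pulse validation), R-peak
    and systolic-peak detection, rule-based premature ventricular contraction
    labeling, heart rate turbulence (turbulence onset and slope), time- and
    frequency-domain heart rate and pulse rate variability (RMSSD, Lomb-Scargle
    LF/HF), baroreflex sensitivity by phase-rectified signal averaging and by
    autoregressive-exogenous spectral gain, pulse-rate/blood-pressure coherence,
    age- and sex-standardized composite classification of autonomic dysfunction,
    and a fully deterministic synthetic waveform generator with ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'waveform-record.R'
    'wfdb.R'
    'beats.R'
    'ecg-image.R'
    'templates.R'
    'sqi.R'
    'abp-quality.R'
    'beat-detection.R'
    'pvc.R'
    'hrv.R'
    'hrt.R'
    'prsa.R'
    'arx.R'
    'coherence.R'
    'reference-ranges.R'
    'ead.R'
    'synthetic.R'
    'pipeline.R'
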