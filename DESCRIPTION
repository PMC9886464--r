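Package: pcgdx
Title: Heart Valve Disease Screening from Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for computer-aided screening of heart valve disease from
    phonocardiogram (heart sound) recordings. Provides WAV ingestion with
    polyphase resampling to 8000 Hz and z-score normalization, a synthetic
    phonocardiogram simulator for five diagnostic classes (normal, aortic
    stenosis, mitral stenosis, mitral regurgitation, mitral valve prolapse),
    extraction of 26 hand-crafted time-domain, spectral-quality and
    mel-frequency cepstral features, chi-square feature ranking with
    importance score -ln(p), a distance-weighted k-nearest-neighbour
    classifier, generalized Morse wavelet scalogram images for transfer
    learning, one-vs-rest diagnostic metrics (accuracy, sensitivity,
    specificity, F1), and a command-line interface chaining all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    png,
    EBImage,
    optparse,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
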