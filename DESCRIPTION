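Package: scmtf
Title: Structured Coupled Matrix-Tensor Factorization of EEG-fMRI Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint decomposition of an EEG spectrogram tensor and an fMRI
    region-of-interest time series matrix into shared neural sources with
    adaptive, region-specific hemodynamic response functions (HRFs). The
    pipeline covers multi-channel Wiener filter enhancement of interictal
    epileptic discharges in the EEG, multitaper tensorization, a structured
    coupled matrix-tensor factorization with Toeplitz-structured
    neurovascular coupling, nonparametric statistical mapping of the fMRI
    spatial signatures via wavelet-resampled surrogate data, and HRF
    deviance biomarkers (extremity and entropy) for localizing
    epileptogenic regions. A synthetic-data generator with known ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    tibble,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti
Config/testthat/edition: 3
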