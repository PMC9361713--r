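Package: emgclean
Title: Single-Channel Attenuation of Facial EMG Artifacts in EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for removing facial electromyographic (EMG) contamination
    from single-channel electroencephalographic (EEG) recordings. Implements
    detrending and outlier replacement, six signal decompositions (EMD, EEMD,
    SSA, CiSSA, coif5 wavelet multiresolution, EMD-PCA), soft-thresholding
    against noise-region statistics to build EMG and EEG reference signals,
    adaptive noise cancellation (LMS, NLMS, RLS, batch Wiener), automatic EMG
    burst detection, and time- and frequency-domain evaluation features
    (windowed-RMS gain ratios, Yule-Walker spectra, median frequency, and a
    normalized-distance contamination metric). Includes a protocol-faithful
    synthetic generator of EEG+EMG mixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
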