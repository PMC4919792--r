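Package: selsort
Title: Selective Spike Sorting for Single-Channel Extracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spike detection, clustering and overlap resolution for
    single-channel extracellular voltage traces. Detection recovers the
    combined impulse sequence by cepstrum-of-bispectrum inverse filtering,
    followed by stationary-wavelet denoising and robust thresholding.
    Detected waveforms are decomposed with Haar wavelets, the coefficients
    most deviant from normality (Kolmogorov-Smirnov) form the feature set,
    and clusters are found by super-paramagnetic (Potts-model) clustering
    with an OPTICS alternative. Putative templates are estimated by Toeplitz
    least squares; a whitening filter built from the residual-noise
    autocovariance sharpens a Bernoulli-prior matched-filter likelihood that
    assigns unclustered events, including overlapping spikes, to neurons.
    A generative simulator with full ground truth, benchmark MAT-file I/O
    and evaluation metrics make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
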