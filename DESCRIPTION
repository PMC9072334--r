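Package: degumap
Title: Place-Cell Maps, LFP Bands, and Sharp-Wave Ripples for Rodent CA1 Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tetrode recordings from the rodent
    hippocampus (CA1) during open-field foraging and novel-object-location
    tasks. Builds occupancy-normalized spatial rate maps with Skaggs
    information and split-half stability, classifies cells against
    spike-time-shuffle null distributions, scores object exploration and
    normalized firing rates around object positions, characterizes local
    field potential bands (delta, theta, beta, gamma) by their coupling to
    running speed using Morlet wavelet and Hilbert band amplitudes, measures
    spike-phase locking with circular statistics, and detects sharp-wave
    ripple events during low-theta episodes. Includes a synthetic-session
    generator (Ornstein-Uhlenbeck foraging paths, Gaussian place fields
    driving Poisson spikes, speed-coupled band-limited LFP components, von
    Mises phase-locked spiking, injected ripple transients) so every stage
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
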