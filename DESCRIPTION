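Package: frnetsim
Title: Fast-Ripple Network Metrics, Virtual Resection and RNS Placement
    Simulation for Epilepsy Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes fast-ripple (FR) network biomarkers from detected
    high-frequency-oscillation event catalogs recorded on stereo-EEG
    (SEEG) contacts: resection ratios, a rate-distance spatial network
    radius measure, and two temporal network measures derived from
    mutual-information graphs between FR onset-time event trains.  Trains
    a radial-basis-function support vector machine on the four FR factors
    to label post-operative seizure freedom, simulates iterative spherical
    virtual resections targeting autonomous high-rate FR sites, and
    simulates responsive-neurostimulation (RNS) stimulation-contact
    placement at high-rate FR sites.  Includes exact nonparametric tests,
    two-proportion power analysis, k-means autonomy clustering, and a
    coupled point-process generator of synthetic SEEG patient cohorts
    with ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    withr
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
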