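Package: mesoreach
Title: Water-Reaching Behavior and Mesoscale Cortical Calcium Imaging Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a head-fixed alternating reward/no-reward
    water-reaching task with simultaneous widefield cortical GCaMP imaging.
    Provides trial-timeline bookkeeping and rule-based behavioral
    categorization from markerless pose tracks, reach-trajectory kinematics
    normalized to spout distance, strobed-illumination channel demultiplexing,
    percent dF/F computation with reflectance-based hemodynamic correction,
    atlas-ROI registration, peak-amplitude and activated-area metrics, and a
    synthetic-session simulator with recorded ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
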