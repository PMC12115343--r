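Package: depthresp
Title: Contactless Respiratory Monitoring from Depth-Camera Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates ventilator-equivalent respiratory parameters from
    overhead depth-camera recordings of a patient's thorax. Depth pixels
    inside an oriented-bounding-box region of interest are unprojected
    through a pinhole camera model, each pixel's 3D surface area is
    estimated from its immediate neighbours, and the per-frame sum of
    depth times area yields a thoracic volume signal. After inversion,
    zeroing and FIR low-pass filtering, respiratory cycles are segmented
    into peaks and troughs to derive respiratory rate, tidal volume,
    minute ventilation, inspiratory and expiratory times, the I:E ratio
    and peak flows. A synthetic breathing-torso phantom with analytic
    ground truth makes every stage testable by parameter recovery,
    without a camera or patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pracma,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
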