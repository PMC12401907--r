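Package: octbias
Title: Catheter Bias Morphometry and Dissection Risk Analysis for
    Intravascular OCT Pullbacks
Version: 0.1.0
Authors@R:
    person("OCT", "Morphometry Group", email = "octbias@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying guidewire/imaging-catheter bias in
    cross-sectional intravascular optical coherence tomography (OCT)
    frames of calcified coronary arteries treated by rotational
    atherectomy.  Computes per-frame bias indices (catheter-to-intima and
    catheter-to-media distances along the bias direction and its
    opposite, touch angle, lumen area and diameters, eccentricity, EEM
    metrics), coregisters pre- and post-procedure pullbacks on a 1-mm
    grid by a fiduciary landmark, and runs the discrimination stage:
    empirical ROC curves with DeLong confidence intervals, Youden-optimal
    cutoffs, paired DeLong AUC comparison, inter-observer agreement
    (ICC(2,1), Cohen's kappa), and a cluster-bootstrap sensitivity
    analysis.  A synthetic pullback generator with a mechanistic
    dissection model makes the whole chain testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
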