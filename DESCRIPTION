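Package: pupilnum
Title: Pupillometry of Perceived Numerosity: Stimuli, Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how perceived numerosity modulates the
    pupillary light response. Generates dot-array stimuli in which pairs of
    dots are joined into dumbbells (inducing the connectedness illusion on
    perceived number) while total ink area and convex hull are iteratively
    matched across conditions; forward-simulates pupil and gaze recordings
    from a Gamma pupil response function together with two-alternative
    forced-choice numerosity judgments; preprocesses pupil traces (artifact
    rejection, downsampling, square-window filtering, baseline correction);
    fits a three-predictor general linear model of pupil dynamics with a
    per-observer Gamma kernel; estimates points of subjective equality from
    cumulative-Gaussian psychometric functions and the derived numerosity
    bias index; and reports condition-level statistics (repeated-measures
    ANOVA with partial eta squared, paired tests with Cohen's d, and
    bivariate contour ellipse areas for fixation stability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
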