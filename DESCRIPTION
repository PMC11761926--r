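Package: imcoh
Title: Intermuscular EMG-EMG Coherence Analysis for Standing Balance Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying common neural drive to lower-leg muscles
    during standing balance from multichannel surface electromyography (EMG).
    Implements Welch cross-spectral estimation and magnitude-squared coherence
    (MSC) between muscle pairs, averaging of MSC over conventional neural
    frequency bands (alpha, beta, lower and upper gamma), powerline notch
    filtering, and per-participant Dunnett many-to-one comparisons of
    less-stable standing conditions against an eyes-open feet-together
    baseline with simultaneous 95% confidence intervals. Includes a synthetic
    multichannel EMG generator with a planted band-limited common drive whose
    true intermuscular coherence is known in closed form, reproducing a
    factorial participant-by-condition-by-trial study layout for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    car,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    multcomp,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
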