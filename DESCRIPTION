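Package: ppirank
Title: Ranking Bait-Prey Interactions in TAP/MS Spectral-Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free scoring and ranking of candidate protein-protein
    interactions from tandem affinity purification mass spectrometry
    (TAP/MS) experiments. Combines normalized spectral abundance (NSAF),
    a reproducibility-weighted detection-frequency term, and a per-pair
    false-discovery-rate calibration derived from a rank-sum comparison
    against negative-control purifications. Includes CompPASS-style Z and
    weighted-D baseline scores, singleton and contaminant-class filters,
    an evaluation protocol against known-interaction references (BioGRID
    TAB format), and a synthetic TAP/MS experiment generator with planted
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), optparse, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
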