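Package: twnrencod
Title: Binding-Site Comparison via Topological Water-Network Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects 3-membered hydrogen-bonded water rings (topological
    water networks) in restrained-solvent molecular dynamics frames using
    TIP3P pair interaction energies, encodes each frame as distance
    classes between ring centroids and binding-site backbone atoms,
    greedily reorders one protein's frames against another's, and scores
    binding-site similarity as the fraction of matched distance classes.
    Ships a synthetic-trajectory generator with planted water rings for
    end-to-end validation without running molecular dynamics, plus
    correlation utilities for relating pairwise similarities to
    inhibitory-activity differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
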