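Package: blsentropy
Title: Branch Length Similarity Entropy Profiles and Shape Self-Similarity
Version: 0.1.0
Authors@R: person("BLS", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Contour-based shape descriptors built on branch length
    similarity (BLS) entropy. Computes the per-node BLS entropy profile of
    a 2D shape boundary, the windowed slope self-similarity statistic
    Gamma, and the cyclic-correlation group statistic Z, together with
    synthetic contour generators (segmented lines, triangles, regular and
    random polygons, template-plus-noise shape groups), Moore-neighbour
    boundary tracing of binary masks, arc-length resampling, and a
    command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
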