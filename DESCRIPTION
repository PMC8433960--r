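Package: siamdiss
Title: Dissimilarity-Space Image Classification with Siamese Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prototype-based dissimilarity-space classification of labeled
    image collections. Small convolutional Siamese networks (weight-tied
    backbones with an absolute-difference head) are trained with either a
    binary cross-entropy pair objective or a clipped triplet objective,
    using Adam or one of two adaptive-gradient variants (DGrad and its
    impulse/decay-modulated extension DecayDGrad). Each image is then
    re-represented by its dissimilarities to a set of k-means prototypes,
    either through the network head directly (FULLY) or through a tapped
    deeper convolutional layer compressed per channel by a 9 x 9 low-frequency
    discrete cosine transform block and compared by cosine distance (DEEPER).
    The resulting dissimilarity vectors train radial-basis-function support
    vector machines whose class scores are fused by the average rule; scores
    from external classifiers can be standardized and fused by the sum rule.
    A synthetic texture-image generator makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
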