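Package: qtcouple
Title: Coupling of Tertiary and Quaternary Motions in Multi-Chain
    Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies allosteric coupling between local (tertiary) and
    global (quaternary) motions in trajectories of multi-chain proteins
    such as hemoglobin. A trajectory is decomposed, by per-chain
    least-squares superposition onto a reference structure, into two
    exactly recombinable parts: a tertiary-only trajectory carrying only
    subunit-internal fluctuations and a quaternary-only trajectory of
    rigid chain poses. Principal component analysis of the quaternary
    part yields the dominant inter-chain mode (cQ); partial-least-squares
    functional mode analysis of the tertiary part against the cQ
    projection yields the maximally correlated internal collective
    coordinate (cT) and its ensemble-weighted variant (cTew).
    Backprojection onto the (cQ, cTew) plane, inter-chain van der Waals
    overlap scoring and distance-based contact classification (pulling,
    pushing, switching) characterise the mechanical coupling pathway.
    Includes a synthetic multi-chain trajectory generator with planted,
    linearly coupled tertiary and quaternary modes for validation, plus
    T-to-R transition detection with outlier screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
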