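Package: stafree
Title: Soft-Tissue-Artifact-Free Assimilation of Periodic Marker Trajectories
    into Planar Multi-Rigid-Link Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assimilates marker-based motion-capture data recorded over one
    cycle of a periodic movement (such as gait) into planar multi-rigid-link
    models in a way that removes the soft tissue artifact (STA). STA profiles
    are assumed periodic and expanded in truncated Fourier series; per-link
    shape parameters are identified from the periodicity of the inter-marker
    distance (a quadratic system solved by Levenberg-Marquardt), after which
    the remaining Fourier coefficients and constant local joint positions
    follow from a single linear joint-constraint least-squares problem. The
    package also provides the uncorrected joint-constraint baseline, a
    seven-link sagittal-plane gait fixture with seeded STA injection, planar
    recursive Newton-Euler inverse dynamics with spectral differentiation,
    TRC/CSV marker file input and output, and evaluation tools for joint
    angles, joint torques, and recovered link lengths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
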