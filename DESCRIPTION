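Package: isodose
Title: Reconstruct and Render Megavoltage Photon Beam Dose Planes from
    Depth-Dose and Profile Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the full two-dimensional relative absorbed-dose
    distribution of a divergent megavoltage photon beam in a water phantom
    from two one-dimensional inputs: a central-axis percentage depth dose
    (PDD) curve and a single off-axis dose profile at the depth of maximum
    dose. Off-axis positions are rescaled between depths along the fan
    lines of the diverging beam, and the dose at every pixel is the product
    of the interpolated PDD and off-axis ratio. Includes grayscale and
    HSI-colour isodose rendering with decile banding and contour
    extraction, an analytic 18 MV beam fixture generator for validation,
    and in-field/penumbra agreement reporting between dose planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
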