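Package: sscmap
Title: Reliable Pixel-Wise Soluble-Solids-Content Mapping from NIR Hyperspectral Images
Version: 0.1.0
Authors@R: person("sscmap", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for chemometric mapping of soluble solids content (SSC,
    Brix) on curved fruit from near-infrared hyperspectral image cubes.
    Implements shape-aware radiometric correction (white/dark calibration,
    inverse-square height correction, Lambertian cosine correction), region
    of interest extraction by PCA score thresholding with Otsu binarization,
    an eight-pattern Savitzky-Golay/SNV preprocessing battery, PLS regression
    with stratified splitting and one-standard-error latent variable
    selection, pixel-wise SSC prediction, a Mahalanobis-distance imaging
    reliability index in PLS score space, and fusion of SSC maps with height
    maps into 3D point clouds. Includes a synthetic phantom generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
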