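Package: mpac
Title: Multipass Active Contours for Adaptive Contour Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatially adaptive contour maps for single-channel images,
    aimed at intensity-ordered topographic analysis of biomedical images
    such as mammograms. A two-phase piecewise-constant (Chan-Vese) level-set
    segmentation with an internal signed-distance penalty (no
    re-initialization required) is applied recursively: each pass bisects
    the current base region into a darker outer shell and a brighter inner
    core, and the inner core becomes the next base region. The nested
    zero-level contours accumulated over all passes form an adaptive contour
    map together with its region-inclusion tree. Includes ROF
    total-variation denoising, a synthetic phantom generator with
    ground-truth masks, image readers and writers (PNG/PGM/TIFF in,
    PNG/CSV/JSON out) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
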