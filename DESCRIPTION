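Package: chromentropy
Title: Shannon Entropy of Gray-Level Histograms for Skin Lesion Color
    Variegation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies color variegation in pigmented skin lesions as the
    Shannon entropy (in bits) of the 256-level grayscale histogram of a
    polygonal region of interest, and as the relative entropy against a
    perilesional-skin internal control.  Reads 8-bit PNG, TIFF and JPEG
    photographs, ImageJ/Fiji .roi polygon files and a portable polygon-JSON
    dialect; rasterizes polygons at pixel centers under the even-odd rule;
    generates synthetic phantom images with analytically known histograms
    and entropies for validation; and ships a command-line interface for
    per-ROI entropy, lesion-versus-control comparisons, batch runs and
    phantom generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    jpeg,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    tiff,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
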