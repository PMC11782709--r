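Package: pcsteady
Title: Steady-State Background Phase Effects in Phase-Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Isochromat Bloch simulation of prospectively triggered
    phase-contrast gradient-echo sequences (FISP and FLASH contrast,
    TR- and ECG-interleaved flow encoding) for studying the background
    phase errors that steady-state disruption introduces into velocity
    quantification. Includes a synthetic phantom renderer that applies
    the single-voxel simulation per pixel under a smooth spatial
    background-phase field, the image-based static-tissue second-order
    polynomial background-phase correction with flow-rate analysis, and
    scripted experiments demonstrating when and how the correction fails.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
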