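Package: desmile
Title: Spectral Smile and Tilt Correction for Push-Broom Hyperspectral
    Imagers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Laboratory-free correction of spectral smile and slit-tilt
    aberrations in push-broom hyperspectral imagers. Emission lines of a
    sharp-lined light source are located by per-row peak detection, a
    circular arc is fitted to each line, and the arc geometry yields a
    per-pixel shift matrix that straightens the lines by row-wise
    interpolation. Includes a synthetic sensor-frame generator with
    controlled tilt and curvature for validation, tilt and curvature
    metrics, image-cube utilities (reflectance from dark and white
    references, false-color reconstruction, spectral angle mapping), a
    self-describing cube container, and a command-line front end driven by
    a plain-text control file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
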