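Package: coflowrheo
Title: Coflowing-Stream Microfluidic Viscometry and RBC Aggregation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Image-to-rheology pipeline for a three-channel microfluidic chip
    that measures blood viscosity and red blood cell (RBC) aggregation during
    continuous syringe delivery. Recovers depth-averaged blood velocity from
    timelapse frame bursts by windowed cross-correlation (micro-PIV), channel
    intensities and the blood/reference coflow interface by Otsu binarization,
    and converts these into calibrated flow rates, blood viscosity via the
    coflowing-stream (virtual wall) model with an empirical correction factor,
    shear rate, and a continuous RBC aggregation index. A physics-based
    synthetic chip renderer generates ground-truthed multi-page TIFF datasets
    (syringe sedimentation, aggregation-induced intensity deficits, interface
    motion, on-off delivery schedules) so every stage of the pipeline can be
    verified without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
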