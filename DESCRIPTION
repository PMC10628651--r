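Package: phycofilm
Title: Growth, Photophysiology and Structure of Microalgal Biofilms
    Under Light/Dark Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of phototrophic biofilms grown under
    square-wave light/dark cycles in flow-cell systems. Estimates net
    specific growth rates from light-transmittance time series via the
    Lambert-Beer double-log regression, fits the Haldane (substrate
    inhibition) growth-irradiance model with an intermittent-light and
    respiration extension, processes pulse-amplitude-modulation (PAM)
    fluorometry traces into quantum yields and rapid-light-curve
    parameters, computes COMSTAT-style structural metrics (biovolume,
    thickness, roughness) from binary confocal stacks, and predicts
    yield and footprint productivity of rotating biofilm reactors.
    Includes a seeded synthetic-data generator that emulates the full
    experimental design for testing and demonstration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
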