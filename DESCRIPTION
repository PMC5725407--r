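Package: tritone
Title: Triple-Tone Sonification of PET Brain Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts PET-derived brain voxel volumes into three-oscillator
    audio renderings whose beating pattern encodes the metabolic deviation
    of the frontal and parietal lobes from the sensorimotor cortex.
    Provides readers for a line-oriented voxel text format and straight-line
    lobe boundary files, white-matter masking at a bit-depth-scaled
    threshold, polygon rasterization of lobe boundaries, the triple-tone
    frequency mapping with severity-dependent detune factors, triangular-wave
    additive synthesis to 16-bit WAV, spectral and beat-envelope analysis
    utilities, and a seeded synthetic phantom generator with known per-lobe
    hypometabolism for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
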