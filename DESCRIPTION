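Package: btikit
Title: Refraction-Corrected Backscatter Tensor Imaging of Fibrous Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for backscatter tensor imaging (BTI) of layered fibrous
    tissue with a rotating linear ultrasound array. Implements two-layer
    refraction-corrected delay-and-sum beamforming for coherent plane-wave
    compounding (exact Snell/Fermat interface crossings), time-of-flight
    estimation of fluid and tissue sound speeds, tissue thickness and
    interface depth from reference-reflector and surface echoes, spatial
    coherence-factor mapping over a rotational scan, cosine-fit extraction of
    transmural fiber angle with fractional anisotropy and goodness-of-fit
    metrics, and axial circular statistics. A seeded radio-frequency
    channel-data simulator generates two-layer fibrous phantoms and
    reference-reflector scenes with full ground truth, so the complete
    pipeline is verifiable without acquisition hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
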