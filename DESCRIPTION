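Package: isochron
Title: Connectomic Morphometry of Synaptic Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dendrite, axon and soma synapse morphometry on skeletonized
    electron-microscopy reconstructions: cable-length-normalized spine,
    shaft and filopodia densities on sampled dendrite fragments, somatic
    innervation profiles (synapses and distinct presynaptic axons per
    soma), bouton geometry, excitatory-axon classification, retraction
    bulb detection, mitochondria coverage statistics, and the
    nonparametric comparison statistics used to contrast developmental
    ages. Includes a synthetic annotation-data generator parameterized by
    per-age profiles (species, cortical region, layer, postnatal day) so
    the full pipeline runs end to end on simulated reconstructions with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nortest,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
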