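Package: sulcparc
Title: Connectivity-Based Sulcal Parcellation and Cross-Species Sulcal
    Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two complementary analyses of primate lateral
    frontal cortex anatomy. The first arm parcellates a sulcal region of
    interest from resting-state fMRI: voxelwise Fisher-z connectivity
    fingerprints against whole-brain gray matter, spectral clustering on a
    k-nearest-neighbour similarity graph, silhouette-based selection of the
    number of parcels, and cluster probability maps across runs. The second
    arm quantifies sulcal morphology across species: anteroposterior
    distances of sulcal features to subcortical landmarks normalized by
    brain extent, data-driven landmark assignment, occurrence frequencies,
    and a binomial mixed-model test of species effects on sulcus presence
    with post hoc pairwise contrasts. A synthetic-data module generates
    phantom fMRI runs with planted connectivity zones and four-species
    sulcal tables with known parameters, so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    RNifti,
    lme4,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synthetic.R'
    'preprocess.R'
    'connectivity.R'
    'parcellation.R'
    'morphometry.R'
    'io.R'
    'pipeline.R'
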