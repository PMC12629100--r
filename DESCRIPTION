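Package: arcplan
Title: Automatic Planning of No-Touch Thermal Ablations with a Passive Steerable Needle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric planning of percutaneous no-touch thermal ablation with
    a passive steerable needle whose articulated tip bends along predictable
    arcs when its flexure joints are unlocked. Provides a voxel/surface scene
    model with safety-margin construction and obstacle distance queries,
    admissible skin entry-point preprocessing, curved-tip trajectory
    construction (one insertion, several curved branches sharing a flexion
    point), geometric ablation-volume simulation with coverage and
    healthy-tissue metrics, a multi-criteria plan score, a constrained
    particle-swarm optimizer with a feasible-solution memory (PSAM), a
    Monte-Carlo sampling baseline, synthetic anatomical phantoms for fully
    reproducible experiments, and plan/metrics serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
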