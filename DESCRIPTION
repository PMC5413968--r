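Package: densdelta
Title: Multi-Crystal Electron-Density Comparison and Binding-Event Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical characterization of ensembles of aligned electron
    density maps from many near-identical crystals, as produced by
    crystallographic fragment screens.  Fits a per-voxel normal-normal model
    of the ground-state density (mean map, natural-variation map and
    per-dataset uncertainties), standardizes each dataset against it to give
    Z-maps, detects clusters of significant deviation ("events"), estimates
    the optimal background density correction (BDC) factor for each event by
    contrast maximization, and computes partial-difference event maps that
    isolate the changed (e.g. ligand-bound) state.  Includes ensemble-model
    construction with paired-occupancy conformers, real-space validation
    metrics (RSCC, RSZD surrogate, B-factor ratio, coordinate RMSD), a
    synthetic multi-dataset generator with known ground truth, and an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
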