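Package: scopeflow
Title: File-Watcher Framework for Concurrent Microscope Acquisition,
    Reconstruction and Mosaicking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A headless framework for running automated microscopy
    experiments in which acquisition, image reconstruction and
    visualization are decoupled into independent units synchronized only
    through a shared filesystem. A polling file watcher detects new,
    fully written files and delivers them exactly once to each unit; the
    acquisition unit executes experiment scripts against a restricted
    control API and writes raw camera stacks to Zarr or HDF5 with
    embedded metadata; the reconstruction unit turns each n-frame
    grid-scan stack into one image and writes TIFF plus OME-Zarr; the
    orchestrator assembles reconstructed tiles into an overlap-blended
    mosaic. A virtual grid-scan microscope with a known forward model
    makes every stage testable end-to-end without hardware, and a tiling
    and timelapse planner generates the stage-target sequences used by
    the bundled demo experiments.
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
NeedsCompilation: yes
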