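Package: gridstitch
Title: Feature-Based Stitching of Grid-Acquired Microscopy Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fast feature-based stitching of whole-slide microscopy tile
    grids. Adjacent tiles are registered by matching dominant scale-space
    blob features extracted from a narrow strip of the nominal overlap,
    with a fallback to the full overlap region; translations are screened
    against the mechanically plausible stage range, invalid links are
    repaired from row/column averages, and global tile positions are
    obtained from a minimum spanning tree or shortest path tree over a
    graph weighted by normalized inverse matched-feature counts. Includes
    mosaic composition without blending, evaluation metrics (overlap RMSE,
    centroid distance error, MSE, PSNR), and a ground-truthed synthetic
    tile-grid generator for textured and binary resolution-target images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
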