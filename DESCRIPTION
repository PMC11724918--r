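Package: spheroidsim
Title: Biophysically Motivated Synthetic 3D Microscopy Data for Nuclei and
    Membrane Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates biophysically realistic 3D synthetic training data for
    nuclei and membrane segmentation models. A 3D Cellular Potts Model (CPM)
    evolves a labelled spheroid configuration by Metropolis Monte Carlo
    dynamics under volume, surface-area and contact-energy constraints;
    simulation parameters are calibrated by a grid scan minimising a
    Wasserstein-distance/IoU metric between the start and end of a run.
    Simulated cell borders drive a prototype-based nucleus placement stage and
    an imaging simulation (depth attenuation, point-spread-function blur,
    downsampling, shot and read noise). Label-co-generating GAN objectives
    (conditional and cycle-consistent, with an auxiliary segmentation
    discriminator) and the post-processing that turns a generated binary label
    channel into instance labels are provided, together with quality measures:
    slice-wise Kernel Inception Distance with a pluggable feature extractor,
    and Cell Tracking Challenge style SEG and DET scores. A phantom module
    generates Voronoi-in-sphere label masks and ellipsoidal nucleus prototypes
    so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
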