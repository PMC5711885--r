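Package: scramblefit
Title: Reconstitution Statistics, Quench Kinetics and Subunit Counting for
    Phospholipid Scramblase Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of fluorescence-based phospholipid
    scramblase assays and related single-molecule and structural data.
    Fits dithionite fluorescence-quench traces to an
    exponential-plus-drift model, transforms end-point reductions into
    the probability that a vesicle carries at least one functional
    scramblase, and fits the Poisson vesicle-occupancy model (Gaussian
    vesicle-size ensemble, refractory subpopulation) to estimate the
    molar mass and oligomeric order of the functional unit. Also counts
    photobleaching steps in single-molecule spot traces by
    change-point detection and compares the step distribution with a
    binomial labeling plus coincidence model, and computes residual
    hydrophobic mismatch (RHM) energies of transmembrane helices from a
    structure and a planar hydrophobic-core slab using a sphere-sampling
    solvent-accessible surface area calculation. Synthetic-data
    generators with known ground truth cover every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
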