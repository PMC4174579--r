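Package: notchcis
Title: Cis-Inhibition Kinetics, Availability Assays and Signaling States
    for Notch-Ligand Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic model of mutual cis-inactivation between Notch
    receptors and DSL ligands (Dll1/Delta, Jag1/Serrate) with its
    quasi-steady-state closed form, Fringe glycosyltransferase modulation
    of interaction strengths, and steady-state solvers for one or two
    cis-ligands.  Provides a single-cell availability-assay analysis
    pipeline: image segmentation and background-subtracted per-cell
    quantification, log-binned median profiles with bootstrap confidence
    intervals, effective-ligand and uninduced normalizations, saturation
    and cis-inhibition dose-response fits, per-bin Wilcoxon comparisons,
    and reporter-onset detection for cis-ligand dilution time courses.
    Includes synthetic-data generators for every pipeline input, a
    signaling-state classifier with the inter-state signaling graph, and a
    two-phase dorsal-ventral boundary lattice simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
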