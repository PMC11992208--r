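Package: trssx
Title: Kinetic and Difference-Density Analysis for Time-Resolved Serial
    Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for time-resolved serial synchrotron
    crystallography (TR-SSX) experiments on photoactive proteins.
    Decomposes time-resolved difference absorption spectra into
    intermediate basis spectra and occupancy traces under a sequential
    two-intermediate photocycle model via truncated singular value
    decomposition and variable projection; computes photoexcitation and
    injector-jet geometry budgets from instrument parameters; builds
    sigma-normalised isomorphous Fo-Fo difference Fourier maps from
    amplitude sets and model phases; projects difference density onto the
    protein sequence; estimates errors of density features and coordinate
    separations by bootstrap resampling; and quantifies C-alpha
    displacements between paired dark/light atomic models. Includes
    synthetic-data generators with known ground truth for every input the
    pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
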