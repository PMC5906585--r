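Package: vfheal
Title: Agent-Based Simulation of Vocal Fold Inflammation and Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 3D hybrid agent-based model of acute vocal fold mucosal
    injury and repair.  Mobile inflammatory-cell agents (platelets,
    neutrophils, macrophages, fibroblasts) act on a lattice of tissue
    patches carrying eight diffusing signalling chemicals and three
    extracellular-matrix protein fields.  Chemical diffusion with decay is
    coarse-grained from its second-scale stability limit to the 30-minute
    agent tick by convolving each field with the m-fold self-composed,
    truncated finite-difference stencil, applied by FFT.  Includes a
    deterministic tick orchestrator with an overlap-transparent phase plan,
    strided volume sampling with VTK/CSV export, and automated
    pattern-oriented verification of the simulated healing time course.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
SystemRequirements: fftw3
NeedsCompilation: yes
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
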