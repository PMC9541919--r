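Package: lvflow
Title: Left-Ventricular 4D Flow MRI Fluid-Dynamics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of time-resolved three-directional (4D flow)
    velocity fields of the left ventricle: volume-normalized kinetic energy
    and viscous energy loss (global and regional), hemodynamic forces derived
    from the Navier-Stokes momentum balance with RMS summaries, the
    transversal-to-longitudinal force ratio and the early-diastolic filling
    impulse, and pathline-based subdivision of the end-diastolic blood pool
    into direct flow, retained inflow, delayed ejection flow and residual
    volume. Includes analytic flow fields with closed-form energetics and a
    contracting-ellipsoid left-ventricle phantom with known ground truth, so
    the whole pipeline is testable without any acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
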