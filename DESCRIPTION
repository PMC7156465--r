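Package: iomorph
Title: Morphometry and Tensile Analysis of the Forearm Interosseous Membrane
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for three-dimensional morphometry of the forearm
    interosseous membrane (IOM) and its individual ligaments from
    triangulated surface meshes, and for the analysis of tensile
    force-displacement curves of ligament specimens. Implements bone-axis
    estimation, fibre direction vectors and signed fan-out angles,
    plane-clipping separation of individual ligaments from the membrane
    sheet, cross-sectional thickness profiling, attachment locations and
    widths on the bone axes, trapezoidal cross-sectional area, biphasic
    peak detection, linear-region stiffness and ultimate strain. A
    parametric forearm phantom and synthetic tensile-curve generator
    provide analytic ground truth for every measurement stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
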