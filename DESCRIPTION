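Package: bearingrrt
Title: Mobile-Bearing Dislocation Analysis via Rapidly-Exploring Random
    Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses the risk of mobile-bearing dislocation in
    unicompartmental knee replacement by rigid-body motion planning. The
    bearing is treated as a free-flying robot between the femoral and
    tibial components; a rapidly-exploring random tree (RRT) planner
    searches for a collision-free escape path for each relative placement
    of the components, and a directional grid sweep reports the minimum
    vertical Distraction to Dislocation (DD) as a function of mediolateral
    component translation. Includes a parametric synthetic implant
    generator (flat tibial plateau with spherical dome and raised medial
    wall, biconcave mobile bearing, spherical femoral condyle segment),
    STL input/output, analytic ball-over-wall oracle scenes, and the
    inter-method agreement statistics (two-way random-effects consistency
    ICC and Bland-Altman summaries) used to validate planner-derived DD
    against mechanical-rig measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
NeedsCompilation: yes
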