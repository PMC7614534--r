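Package: tissuesim
Title: Multi-Framework Cell-Based Tissue Simulation in Two Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained two-dimensional tissue simulator implementing five
    discrete cell-based modelling frameworks behind one simulation loop: the
    cellular automaton, the cellular Potts model, cell-centre models with cells
    represented as overlapping spheres or as Voronoi tessellations, and the
    vertex model. Includes a planar geometric kernel (polygon measures,
    Delaunay/Voronoi tessellation, honeycomb mesh and lattice generators), a
    cell-cycle model hierarchy, vertex-model T1/T2 rearrangements and cell
    division, Metropolis dynamics with differential adhesion, modifier and
    writer hooks, reproducible seeded runs, VTK unstructured-grid (VTU/PVD)
    time-series output, JSON scenario configuration, and a command-line entry
    point with bundled demonstration scenarios including differential-adhesion
    cell sorting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    ggplot2,
    rlang,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
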