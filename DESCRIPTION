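Package: tumorvox
Title: Voxel-Lattice Stochastic Simulation of Three-Dimensional Tumor Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular discrete-time stochastic simulator of three-dimensional
    tumor growth in an inhomogeneous, time-varying chemical environment. The
    tissue is discretized into an N x N x N voxel lattice whose per-voxel state
    (live and necrotic cell populations, oxygen and glucose stocks, vascular
    supply rates and capacities) evolves under sequentially applied operators
    for vascular remodeling, metabolism-driven proliferation and necrosis,
    chemical diffusion, and overflow-driven tumor-cell invasion. Diffusion
    operators are sparse voxel-transition matrices whose entries are Monte
    Carlo estimates of stochastic-differential-equation transition kernels,
    assembled under fixed Dirichlet or reflecting (homogeneous Neumann)
    boundary conditions. Includes a glycolysis/combustion (Warburg-effect)
    metabolism model, tumor-induced angiogenesis and vessel regression,
    ensemble simulation with survival-probability summaries, and plotting of
    planar tumor sections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
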