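Package: emassemble
Title: Simultaneous Rigid-Body Assembly of Macromolecular Complexes into
    Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-component rigid fitting of coarse-grained protein
    subunits into low-resolution cryo-EM density maps. Implements a
    Gaussian-overlap fitting energy with precomputed overlap grids and
    per-bead maximum-overlap calibration, voxel atom density clash
    penalties, gradient vector matching (3D Prewitt) scoring, cyclic and
    dihedral symmetry distance-equality restraints, location and gravity
    restraints, rigid-body quasi-Newton energy minimization, and a staged
    assembly protocol with combinatorial recombination of partial
    solutions. Includes density map simulation, filtering, deconvolution
    and MRC/Situs map I/O, plus a synthetic toy-assembly generator with
    known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
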