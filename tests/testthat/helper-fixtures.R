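# Shared fixtures: tiny bead models, a one-ring toy, and handcrafted PDB
# text. Everything is generated in code under fixed seeds.

tiny_model <- function(n = 12, seed = 7, spread = c(6, 4, 3)) {
  set.seed(seed)
  xyz <- cbind(rnorm(n, 0, spread[1]), rnorm(n, 0, spread[2]),
               rnorm(n, 0, spread[3]))
  coarse_model(xyz, weight = runif(n, 2, 4),
               kind = rep(c("CA", "SC"), length.out = n),
               residue = rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)],
               name = "tiny")
}

one_ring_spec <- function(X = 7, seed = 11) {
  toy_spec(rings = list(list(X = X, radius = 30, Z = 0, n_beads = 12,
                             spread = c(10, 5, 2))), seed = seed)
}

# minimal two-residue PDB text (ALA then GLY), chain A + one chain B atom
write_tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       4.001   2.830   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.504   2.705   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.110   1.635   0.000  1.00  0.00           O",
    "ATOM     10  CA  ALA B   1      10.000  10.000  10.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

# random rigid perturbation of one pose
perturb_pose <- function(pose, trans = 1, angle = 0.2) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  p <- rigid_pose(rotation_from_axis_angle(ax * angle), rnorm(3, 0, trans))
  pose_compose(p, pose)
}

# finite-difference force check for an energy function f(cc) ->
# list(energy, forces); returns max relative error over ntest probes.
fd_force_error <- function(f, cc, ntest = 10, h = 1e-5, nudge = TRUE) {
  ev <- f(cc)
  err <- 0
  n <- nrow(cc$xyz)
  for (t in seq_len(ntest)) {
    i <- sample.int(n, 1); ax <- sample.int(3, 1)
    cp <- cc; cp$xyz[i, ax] <- cp$xyz[i, ax] + h
    cm <- cc; cm$xyz[i, ax] <- cm$xyz[i, ax] - h
    fd <- -(f(cp)$energy - f(cm)$energy) / (2 * h)
    err <- max(err, abs(fd - ev$forces[i, ax]) / (abs(fd) + 1e-9))
  }
  err
}

# keep bead coordinates away from voxel cell faces so central differences
# do not straddle a trilinear-derivative kink
nudge_off_faces <- function(xyz, origin, voxel, margin = 0.02) {
  u <- sweep(xyz, 2, origin) / voxel
  frac <- u - floor(u)
  for (a in 1:3) {
    lo <- frac[, a] < margin
    hi <- frac[, a] > 1 - margin
    xyz[lo, a] <- xyz[lo, a] + margin * voxel
    xyz[hi, a] <- xyz[hi, a] - margin * voxel
  }
  xyz
}
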