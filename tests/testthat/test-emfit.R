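test_that("gaussian_overlap matches the 3D product-integral oracle", {
  g5 <- list(sigma = 5, s = 1 / 50, amplitude = 1)
  got <- gaussian_overlap(3, g5, g5)
  # brute-force separable Riemann integral of the two Gaussians' product
  h <- 0.25; xs <- seq(-30, 33, by = h)
  ix <- sum(exp(-xs^2 / 50) * exp(-(xs - 3)^2 / 50)) * h
  i0 <- sum(exp(-xs^2 / 50)^2) * h
  expect_equal(got$O, ix * i0 * i0, tolerance = 1e-4 * ix * i0 * i0)

  # strictly decreasing in D, maximum at D = 0
  D <- seq(0, 20, by = 0.5)
  O <- gaussian_overlap(D, g5, g5)$O
  expect_true(all(diff(O) < 0))
  # symmetric under parameter swap
  ga <- list(sigma = 4, s = 1 / 32, amplitude = 2)
  gb <- list(sigma = 7, s = 1 / 98, amplitude = 0.5)
  expect_equal(gaussian_overlap(5, ga, gb)$O, gaussian_overlap(5, gb, ga)$O)
  # derivative consistent with the closed form
  expect_equal(got$dO_dD, -2 * got$gamma * 3 * got$O)
  expect_error(gaussian_overlap(1, list(s = 0, amplitude = 1),
                                list(s = 0, amplitude = 1)), "positive")
})

test_that("precompute_overlap_grid reduces to the analytic pair overlap", {
  d <- c(9, 9, 9)
  v <- array(0, d); v[5, 5, 5] <- 2.5    # single occupied voxel
  map <- density_grid(v, origin = c(0, 0, 0), voxel_size = 10)
  ap <- gaussian_params(40)
  og <- precompute_overlap_grid(map, ap, upsample = 1L)
  center <- c(40, 40, 40)
  for (ijk in list(c(5, 5, 5), c(1, 1, 1), c(9, 3, 6))) {
    Dv <- sqrt(sum(((ijk - 1) * 10 - center)^2))
    pair <- gaussian_overlap(Dv, ap, list(s = ap$s, amplitude = 2.5))$O
    expect_equal(og$O[ijk[1], ijk[2], ijk[3]], pair, tolerance = 1e-6 * pair)
  }
  # all-zero map -> all-zero grid; linearity in map values
  zg <- precompute_overlap_grid(density_grid(array(0, d), voxel_size = 10),
                                ap, upsample = 1L)
  expect_true(all(zg$O == 0) && all(zg$gx == 0))
  og2 <- precompute_overlap_grid(rescale_to_sum(map, 5), ap, upsample = 1L)
  expect_equal(og2$O, 2 * og$O, tolerance = 1e-12)
})

test_that("interpolated overlap matches direct summation to 1e-3", {
  m <- tiny_model(20, seed = 21, spread = c(8, 6, 5))
  mp <- simulate_map(m, 40)
  ap <- gaussian_params(40)
  og <- precompute_overlap_grid(mp, ap)
  set.seed(22)
  pos <- cbind(runif(100, -30, 30), runif(100, -30, 30), runif(100, -30, 30))
  ip <- interpolate_overlap(og, pos)
  dr <- direct_overlap(mp, ap, pos)
  expect_lt(max(abs(ip$O - dr$O) / dr$O), 1e-3)
  # stored gradient field tracks the true gradient
  expect_lt(max(abs(ip$grad - dr$grad)) / max(abs(dr$grad)), 0.05)
  # weights: 8 per position, sum to 1
  expect_equal(rowSums(ip$weights), rep(1, 100), tolerance = 1e-12)
  # exactly at a stored voxel center: that voxel's value
  p0 <- matrix(og$origin + og$voxel_size * c(3, 4, 5), 1)
  ip0 <- interpolate_overlap(og, p0)
  expect_equal(ip0$O, og$O[4, 5, 6], tolerance = 1e-12)
  expect_equal(sort(ip0$weights[1, ], decreasing = TRUE)[1], 1)
  # out-of-grid positions are flagged
  far <- matrix(og$origin - 50, 1)
  expect_false(interpolate_overlap(og, far)$inside)
})

test_that("midpoint interpolation averages adjacent centers in linear fields", {
  # a linear ramp has constant gradient, where the gradient-corrected
  # interpolant reduces to plain trilinear weighting
  d <- c(6, 6, 6)
  xs <- (seq_len(6) - 1) * 2
  vals <- array(rep(xs, 36), d)
  og <- structure(list(O = vals, gx = array(1, d), gy = array(0, d),
                       gz = array(0, d), origin = c(0, 0, 0), voxel_size = 2,
                       dims = d), class = "overlap_grid")
  mid <- matrix(c(3, 4, 4), 1)   # halfway between x-neighbours
  ip <- interpolate_overlap(og, mid)
  expect_equal(ip$O, (og$O[2, 3, 3] + og$O[3, 3, 3]) / 2, tolerance = 1e-12)
})

test_that("calibration reproduces the self overlap and orders beads", {
  # single bead: maximum overlap = self pair overlap at D = 0
  m1 <- coarse_model(matrix(0, 1, 3), weight = 2)
  cal <- calibrate_max_overlap(m1, 40)
  ap <- gaussian_params(40)
  self0 <- 2 * gaussian_overlap(0, ap, ap)$O   # weight * unit-pair overlap
  expect_equal(cal$max_overlap, self0, tolerance = 1e-3 * self0)

  # a core bead spills more than an isolated distant bead of equal weight
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(-4, 0, 0), c(0, 4, 0), c(0, -4, 0),
               c(60, 0, 0))
  mc <- coarse_model(xyz, weight = rep(2, 6))
  calc <- calibrate_max_overlap(mc, 40)
  expect_gt(calc$max_overlap[1], calc$max_overlap[6])

  # deterministic: two runs bit-identical
  expect_identical(calibrate_max_overlap(mc, 40)$max_overlap,
                   calc$max_overlap)
})

test_that("em_fit_energy is zero at the calibration pose and minimal there", {
  m <- tiny_model(16, seed = 23)
  selfmap <- simulate_map(m, 40)
  src <- deconvolve(selfmap, sigma_from_resolution(40))
  og <- precompute_overlap_grid(src, gaussian_params(40))
  asm <- assembly(list(m))
  tab <- max_overlap_table(asm, 40, F = 1)
  e0 <- em_fit_energy(asm, og, tab)
  expect_lt(abs(e0$energy), 1e-6 * 100 * sum(tab$max_overlap^2) /
              mean(tab$max_overlap^2))
  set.seed(24)
  worse <- vapply(1:50, function(i) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    tr <- rnorm(3); tr <- tr / sqrt(sum(tr^2)) * runif(1, 5, 20)
    a2 <- assembly(list(m), list(rigid_pose(
      rotation_from_axis_angle(ax * runif(1, 0, 1)), tr)))
    em_fit_energy(a2, og, tab)$energy
  }, 0)
  expect_true(all(worse > e0$energy))
  expect_error(max_overlap_table(asm, 40, F = 0.5), "F")
})

test_that("em_fit forces match finite differences; outside beads are pulled in", {
  m <- tiny_model(14, seed = 25)
  mp <- simulate_map(m, 40)
  src <- deconvolve(mp, sigma_from_resolution(40))
  og <- precompute_overlap_grid(src, gaussian_params(40))
  asm <- assembly(list(m))
  tab <- max_overlap_table(asm, 40)
  a2 <- assembly(list(m), list(rigid_pose(t = c(4.3, -2.7, 3.1))))
  cc <- assembly_coords(a2)
  cc$xyz <- nudge_off_faces(cc$xyz, og$origin, og$voxel_size)
  set.seed(26)
  err <- fd_force_error(function(cc) em_fit_energy(cc, og, tab), cc,
                        ntest = 20)
  expect_lt(err, 1e-4)

  # a bead far outside: full deficiency, force points back toward the map
  for (probe in list(og$origin - 40,                       # corner diagonal
                     c(mean(m$xyz[, 1]), mean(m$xyz[, 2]),
                       og$origin[3] - 30))) {              # below a face
    ccf <- cc
    ccf$xyz[1, ] <- probe
    ev <- em_fit_energy(ccf, og, tab)
    toward <- og$centroid - probe
    cosang <- sum(ev$forces[1, ] * toward) /
      sqrt(sum(ev$forces[1, ]^2) * sum(toward^2))
    expect_gt(cosang, 0.3)
  }
})

test_that("voxel atom density deposits trilinear weights conservatively", {
  geo <- density_grid(array(0, c(8, 8, 8)), origin = c(0, 0, 0),
                      voxel_size = 5)
  m1 <- coarse_model(matrix(c(15, 15, 15), 1, 3), weight = 1)
  vg <- accumulate_voxel_density(assembly(list(m1)), geo)
  expect_equal(vg$values[4, 4, 4], 1)
  expect_equal(sum(vg$values), 1)
  # bead at a cell corner: eight voxels x 1/8
  m2 <- coarse_model(matrix(c(12.5, 12.5, 12.5), 1, 3), weight = 1)
  vg2 <- accumulate_voxel_density(assembly(list(m2)), geo)
  expect_equal(sort(vg2$values[vg2$values > 0]), rep(0.125, 8))
  # random assembly: total deposited = total weight
  set.seed(27)
  m3 <- coarse_model(matrix(runif(30, 5, 30), 10, 3), weight = runif(10, 1, 3))
  vg3 <- accumulate_voxel_density(assembly(list(m3)), geo)
  expect_equal(sum(vg3$values), sum(m3$weight), tolerance = 1e-9)
  # out-of-grid beads deposit nothing and are counted
  m4 <- coarse_model(rbind(c(15, 15, 15), c(500, 0, 0)), weight = c(1, 1))
  vg4 <- accumulate_voxel_density(assembly(list(m4)), geo)
  expect_equal(sum(vg4$values), 1)
  expect_equal(attr(vg4, "n_outside"), 1L)
})

test_that("density clash penalty activates above the cap and separates beads", {
  geo <- density_grid(array(0, c(10, 10, 10)), origin = c(-25, -25, -25),
                      voxel_size = 5)
  # below cap: zero energy and forces
  m <- coarse_model(rbind(c(0.3, 0.2, 0.1), c(6.1, 0.4, 0.2)),
                    weight = c(1, 1))
  r <- density_clash_energy(assembly(list(m)), geo, cap = 5)
  expect_equal(r$energy, 0)
  expect_true(all(r$forces == 0))

  # two co-located beads whose combined (but not single) weight exceeds
  # the cap: positive energy that decreases to zero as they separate
  # (whole-voxel steps keep the per-bead trilinear deposits identical)
  sep_energy <- vapply(seq(0, 4) * geo$voxel_size, function(s) {
    mm <- coarse_model(rbind(c(0.3, 0.2, 0.1), c(0.3 + s, 0.2, 0.1)),
                       weight = c(4, 4))
    density_clash_energy(assembly(list(mm)), geo, cap = 5)$energy
  }, 0)
  expect_gt(sep_energy[1], 0)
  expect_true(all(diff(sep_energy) <= 1e-9))
  expect_equal(sep_energy[5], 0)
  expect_error(density_clash_energy(assembly(list(m)), geo, cap = -1), "cap")

  # force/energy consistency off cell faces
  set.seed(28)
  mm <- coarse_model(matrix(runif(18, -8, 8), 6, 3) + 0.21,
                     weight = runif(6, 2, 5))
  cc <- assembly_coords(assembly(list(mm)))
  cc$xyz <- nudge_off_faces(cc$xyz, geo$origin, geo$voxel_size)
  err <- fd_force_error(function(cc)
    density_clash_energy(cc, geo, cap = 0.5, k_clash = 2)[c("energy",
                                                            "forces")],
    cc, ntest = 15)
  expect_lt(err, 1e-4)
})

test_that("em terms are invariant under joint rigid transforms of assembly and map", {
  m <- tiny_model(12, seed = 29)
  asm <- assembly(list(m))
  mp <- simulate_map(m, 40)
  src <- deconvolve(mp, sigma_from_resolution(40))
  og <- precompute_overlap_grid(src, gaussian_params(40))
  tab <- max_overlap_table(asm, 40)
  a2 <- assembly(list(m), list(rigid_pose(t = c(3.7, -2.2, 1.9))))
  e_orig <- em_fit_energy(a2, og, tab)$energy

  # transform assembly and re-simulate the map in the transformed frame
  p <- rigid_pose(rotation_from_axis_angle(c(0.4, -0.2, 0.7)), c(11, -6, 3))
  mT <- coarse_model(transform_xyz(m$xyz, p), m$weight, m$kind, m$residue)
  mpT <- simulate_map(mT, 40)
  srcT <- deconvolve(mpT, sigma_from_resolution(40))
  ogT <- precompute_overlap_grid(srcT, gaussian_params(40))
  tabT <- max_overlap_table(assembly(list(mT)), 40)
  shift <- pose_compose(p, pose_compose(rigid_pose(t = c(3.7, -2.2, 1.9)),
                                        pose_inverse(p)))
  a2T <- assembly(list(mT), list(shift))
  e_T <- em_fit_energy(a2T, ogT, tabT)$energy
  expect_equal(e_T, e_orig, tolerance = 0.02 * max(e_orig, 1))
})

test_that("spillover calibration returns F >= 1 and grows with crowding", {
  toy <- make_toy_assembly(one_ring_spec())
  ref <- toy$reference
  mp <- simulate_map(ref, 40)
  src <- deconvolve(mp, sigma_from_resolution(40))
  og <- precompute_overlap_grid(src, gaussian_params(40))
  tab <- max_overlap_table(ref, 40, F = 1)
  Fhat <- calibrate_spillover(ref, og, tab)
  expect_gte(Fhat, 1)
  # with intermolecular spillover the reference achieves at least its
  # intramolecular maxima nearly everywhere
  cc <- assembly_coords(ref)
  ip <- interpolate_overlap(og, cc$xyz)
  ratio <- cc$weight * ip$O / tab$max_overlap
  expect_gt(quantile(ratio, 0.5), 1)
})
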