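test_that("cyclic restraint sets have the right combinatorial structure", {
  # C7: three equalities S1..S3 per bead pair, seven distances each
  r7 <- build_cx_restraints(p = 3, X = 7)
  sets_per_pair <- 3
  n_pairs <- 2                       # beads (1,3) and the middle self-pair
  expect_equal(max(r7$entries$set), sets_per_pair * n_pairs)
  expect_true(all(table(r7$entries$set) == 7))

  # C2: a single equality per pair with two distances
  r2 <- build_cx_restraints(p = 2, X = 2)
  expect_true(all(table(r2$entries$set) == 2))
  expect_equal(max(r2$entries$set), 1 * 1)

  # linear scaling in p, X entries per set, for several (p, X)
  for (p in c(2, 10)) for (X in c(2, 6, 7)) {
    r <- build_cx_restraints(p, X)
    expect_true(all(table(r$entries$set) == X))
    expect_equal(max(r$entries$set), ((p + 1) %/% 2) * floor(X / 2))
    # monomer indices are modulo X
    expect_true(all(r$entries$j2 >= 1 & r$entries$j2 <= X))
  }
  expect_error(build_cx_restraints(3, 1), "X")
})

test_that("D4 restraints enforce the three listed equalities", {
  r <- build_d4_restraints(p = 2)
  expect_true(all(table(r$entries$set) == 2))
  expect_equal(max(r$entries$set), 3)     # one bead pair -> 3 equalities

  # four identical monomers at exact D2 symmetry: zero energy
  m <- coarse_model(rbind(c(2, 0, 0), c(-2, 0.5, 1)), weight = c(1, 1))
  sq <- lapply(list(c(10, 10, 0), c(-10, 10, 0), c(-10, -10, 0),
                    c(10, -10, 0)), function(t) {
    ang <- atan2(t[2], t[1])
    rigid_pose(rotation_from_axis_angle(c(0, 0, ang)), t)
  })
  # order monomers so 1-2 and 3-4 are diagonal pairs of the listed scheme
  asm <- assembly(rep(list(m), 4), sq[c(1, 2, 3, 4)])
  r1 <- build_d4_restraints(p = 1)
  e <- symmetry_energy(asm, r1)
  expect_lt(e$energy, 1e-18)
  # one monomer translated 1 A: positive energy
  asm2 <- asm
  asm2$poses[[2]] <- pose_compose(rigid_pose(t = c(1, 0, 0)), asm2$poses[[2]])
  expect_gt(symmetry_energy(asm2, r1)$energy, 0)
  expect_error(build_d4_restraints(p = 2, components = 1:3), "4 monomers")
})

test_that("symmetry energy vanishes on exact rings and restores deviations", {
  toy <- make_toy_assembly(one_ring_spec())
  rs <- build_cx_restraints(sum(toy$models[[1]]$kind == "CA"), 7)
  e <- symmetry_energy(toy$reference, rs)
  expect_lt(e$energy, 1e-18)
  expect_lt(max(abs(e$forces)), 1e-12)

  # hand case: equality set with distances {4, 6} -> deviations -/+1,
  # force magnitude c = 0.005 on each pair
  mA <- coarse_model(rbind(c(0, 0, 0), c(1, 0, 0)), weight = c(1, 1))
  # monomer 2 placed so d(A1,B2) = 4 and d(A2,B1) = 6
  asm <- assembly(list(mA, mA),
                  list(rigid_pose(), rigid_pose(t = c(6.3, 0, 0))))
  # beads: m1 b1 at 0, m1 b2 at 1; m2 b1 at 6.3, m2 b2 at 7.3
  # d(A1,B2) = |0 - 7.3|... choose a cleaner explicit geometry:
  asm$poses[[2]] <- rigid_pose(t = c(4, 0, 0))
  # now m2 b1 = 4, b2 = 5: d(A1,B2) = |0-5| = 5, d(A2,B1) = |1-4| = 3
  rs2 <- build_cx_restraints(p = 2, X = 2)
  ev <- symmetry_energy(asm, rs2)
  # distances {5,3}: mean 4, deviations +/-1, E = 2 * (1/2 c D^2) = c
  expect_equal(ev$energy, 0.005, tolerance = 1e-12)
  fmax <- apply(abs(ev$forces), 1, max)
  expect_equal(max(fmax), 0.005, tolerance = 1e-9)

  # forces conserve momentum and point downhill
  expect_lt(max(abs(colSums(ev$forces))), 1e-15)
  step <- 0.05
  cc <- assembly_coords(asm)
  e1 <- ev$energy
  cc2 <- cc; cc2$xyz <- cc$xyz + step * ev$forces / max(abs(ev$forces))
  pre <- emassemble:::precompute_symmetry_rows(asm, rs2)
  e2 <- emassemble:::symmetry_energy_fast(cc2, pre)$energy
  expect_lt(e2, e1)
})

test_that("symmetry energy/forces are consistent and transform-invariant", {
  toy <- make_toy_assembly(one_ring_spec(seed = 41))
  asm <- toy$reference
  set.seed(42)
  asm$poses[[3]] <- perturb_pose(asm$poses[[3]], trans = 2, angle = 0.3)
  rs <- build_cx_restraints(sum(toy$models[[1]]$kind == "CA"), 7)
  pre <- emassemble:::precompute_symmetry_rows(asm, rs)
  cc <- assembly_coords(asm)
  err <- fd_force_error(function(cc)
    emassemble:::symmetry_energy_fast(cc, pre), cc, ntest = 15)
  expect_lt(err, 1e-4)

  # invariant under a global rigid transform (no symmetry axis is used)
  g <- rigid_pose(random_rotation(), c(30, -12, 7))
  asm2 <- assembly(asm$models, lapply(asm$poses, function(p)
    pose_compose(g, p)))
  expect_equal(symmetry_energy(asm2, rs)$energy,
               symmetry_energy(asm, rs)$energy, tolerance = 1e-9)
})

test_that("symmetry restraints round-trip through the text format", {
  rs <- build_cx_restraints(p = 5, X = 7, components = 3:9)
  path <- tempfile(fileext = ".txt")
  write_restraints(rs, path)
  rs2 <- read_restraints(path)
  expect_equal(rs2$order, rs$order)
  expect_equal(rs2$c, rs$c)
  expect_equal(rs2$components, rs$components)
  expect_equal(rs2$entries, rs$entries)
  expect_equal(rs2$type, "cyclic")
})

test_that("location restraints pull the COM with the stated constant", {
  m <- tiny_model(8, seed = 43)
  com <- colSums(m$xyz * m$weight) / sum(m$weight)
  asm <- assembly(list(m))
  # COM at target: zero energy
  at <- location_energy(asm, location_restraint(1, com))
  expect_equal(at$energy, 0, tolerance = 1e-18)
  # |d| = 2, k = 0.5 -> |F| = 1 kcal/mol/A, E = 1
  off <- location_energy(asm, location_restraint(1, com + c(0, 0, 2),
                                                 k = 0.5))
  expect_equal(off$energy, 0.5 * 0.5 * 4, tolerance = 1e-12)
  expect_equal(sqrt(sum(colSums(off$forces)^2)), 1, tolerance = 1e-12)
  expect_error(location_energy(asm, location_restraint(5, c(0, 0, 0))),
               "invalid component")

  # uniform(-5,5) per-axis offsets average 4.8 A displacement
  set.seed(44)
  d <- matrix(runif(3e5, -5, 5), ncol = 3)
  expect_equal(mean(sqrt(rowSums(d^2))), 4.8, tolerance = 0.05)
})

test_that("gravity terms balance attraction and repulsion", {
  m <- tiny_model(6, seed = 45)
  two <- function(sep) assembly(list(m, m), list(rigid_pose(),
                                                 rigid_pose(t = c(sep, 0, 0))))
  r0 <- 25
  # exactly at the repulsion radius with no attraction: zero energy
  e_b <- gravity_terms(two(r0), attract_k = 0, repulse_radius = r0)
  expect_equal(e_b$energy, 0, tolerance = 1e-18)
  # distant pair: net attraction along the separation axis
  e_far <- gravity_terms(two(80), attract_k = 0.001, repulse_radius = r0)
  f1 <- colSums(e_far$forces[1:n_beads(m), , drop = FALSE])
  expect_gt(f1[1], 0)                   # pulled toward the partner at +x
  # equilibrium of the two harmonics: r* = kr r0 / (ka + kr)
  ka <- 0.01; kr <- 1
  rstar <- kr * r0 / (ka + kr)
  es <- vapply(seq(rstar - 5, rstar + 5, by = 0.25), function(s)
    gravity_terms(two(s), attract_k = ka, repulse_radius = r0,
                  repulse_k = kr)$energy, 0)
  expect_equal(seq(rstar - 5, rstar + 5, by = 0.25)[which.min(es)], rstar,
               tolerance = 0.3)
  # momentum conserved
  expect_lt(max(abs(colSums(e_far$forces))), 1e-12)
})
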