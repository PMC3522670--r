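small_plan <- function(...) stage_plan(n_starts = 12, preassembly_keep = 8,
                                       scoring_keep = 6, refine_keep = 3,
                                       recombine_top = 4,
                                       preassembly_iter = 25,
                                       assembly_iter = 25, refine_iter = 15,
                                       ...)

test_that("random starts are seed-reproducible and rotation-uniform", {
  models <- list(tiny_model(6, 71), tiny_model(5, 72))
  box <- list(lo = c(-20, -20, -20), hi = c(20, 20, 20))
  p1 <- random_starts(models, 5, box, seed = 3)
  p2 <- random_starts(models, 5, box, seed = 3)
  expect_identical(p1$structures, p2$structures)
  p3 <- random_starts(models, 5, box, seed = 4)
  expect_false(identical(p1$structures[[1]], p3$structures[[1]]))
  expect_error(random_starts(models, 2, list(lo = c(0, 0, 0),
                                             hi = c(0, 0, 0))), "empty box")

  # orientation uniformity: the mean rotation matrix tends to zero
  set.seed(73)
  msum <- matrix(0, 3, 3)
  n <- 10000
  for (i in seq_len(n)) msum <- msum + random_rotation()
  expect_lt(max(abs(msum / n)), 0.05)
})

test_that("ring topology starts respect the ring geometry", {
  model <- tiny_model(8, 74)
  rings <- list(list(model = model, X = 7, Z = -64.4, radius = 35,
                     radius_jitter = 15, z_jitter = 5))
  pool <- ring_topology_starts(rings, 30, seed = 5)
  expect_identical(ring_topology_starts(rings, 30, seed = 5)$structures,
                   pool$structures)
  com_model <- colSums(model$xyz * model$weight) / sum(model$weight)
  for (i in seq_len(pool_size(pool))) {
    coms <- t(vapply(pool$structures[[i]], function(p)
      as.numeric(p$R %*% com_model) + p$t, numeric(3)))
    radii <- sqrt(coms[, 1]^2 + coms[, 2]^2)
    # radius within 35 +/- 15, shared per ring
    expect_true(all(radii >= 20 - 1e-6 & radii <= 50 + 1e-6))
    expect_lt(diff(range(radii)), 1e-6)
    # shared z within the jitter window
    expect_true(all(abs(coms[, 3] - (-64.4)) <= 5 + 1e-9))
    expect_lt(diff(range(coms[, 3])), 1e-6)
    # exact 7-fold positional symmetry about the z axis
    ang <- sort(atan2(coms[, 2], coms[, 1]))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    expect_equal(gaps, rep(2 * pi / 7, 7), tolerance = 1e-6)
  }
})

test_that("pre-assembly imposes symmetry and truncates the pool", {
  toy <- make_toy_assembly(one_ring_spec(seed = 75))
  rings <- list(list(model = toy$models[[1]], X = 7, Z = 0, radius = 30,
                     radius_jitter = 8, z_jitter = 3))
  pool <- ring_topology_starts(rings, 12, seed = 6)
  rs <- build_cx_restraints(sum(toy$models[[1]]$kind == "CA"), 7)
  pre_med <- median(vapply(seq_len(12), function(i)
    symmetry_energy(pool_assembly(pool, i), rs)$energy, 0))
  out <- pre_assembly_stage(pool, rs, small_plan(), mode = "orientation")
  expect_equal(pool_size(out), 8)
  expect_false(is.unsorted(out$scores$symmetry))
  expect_lt(median(out$scores$symmetry), pre_med)

  # a pool of exact symmetric rings passes through with ~zero energies
  perfect <- structure_pool(toy$reference$models,
                            replicate(3, toy$reference$poses,
                                      simplify = FALSE))
  outp <- pre_assembly_stage(perfect, rs,
                             stage_plan(n_starts = 3, preassembly_keep = 3,
                                        scoring_keep = 3, refine_keep = 3),
                             mode = "orientation")
  expect_lt(max(outp$scores$symmetry), 1e-12)
})

test_that("recombination emits every ordered pair x pattern, deduplicated", {
  model <- tiny_model(4, 76)
  mk_pool <- function(P, seed = 7) {
    set.seed(seed)
    structure_pool(rep(list(model), 4),
                   replicate(P, lapply(1:4, function(i)
                     rigid_pose(random_rotation(), rnorm(3, 0, 10))),
                     simplify = FALSE))
  }
  scheme2 <- recombination_scheme(blocks = list(1:2, 3:4),
                                  patterns = list(1))
  out <- recombine(mk_pool(2), scheme2)
  expect_equal(pool_size(out), 2 + 2)      # P(P-1)m = 2 children
  # child count formula for several P and pattern counts
  scheme3 <- recombination_scheme(blocks = list(1, 2:3, 4),
                                  patterns = list(1, 3))
  for (P in c(2, 5, 10)) {
    out <- recombine(mk_pool(P), scheme3)
    expect_equal(pool_size(out), P + P * (P - 1) * 2)
  }
  # identical parents collapse to no new children
  dup <- mk_pool(2)
  dup$structures[[2]] <- dup$structures[[1]]
  expect_equal(pool_size(recombine(dup, scheme2)), 2)
  expect_error(recombination_scheme(list(1:2, 2:4), list(1)), "partition")
  expect_error(recombination_scheme(list(1:2, 3:4), list(1:2)), "proper")
})

test_that("the recombination count reproduces 19800 for 100 parents", {
  model <- coarse_model(matrix(rnorm(9), 3, 3))
  set.seed(8)
  pool <- structure_pool(rep(list(model), 3),
                         replicate(100, lapply(1:3, function(i)
                           rigid_pose(random_rotation(), rnorm(3, 0, 5))),
                           simplify = FALSE))
  scheme <- recombination_scheme(blocks = list(1, 2, 3),
                                 patterns = list(1, 3))
  out <- recombine(pool, scheme, top_p = 100)
  expect_equal(pool_size(out) - 100, 19800)
})

test_that("energy-gap selection cuts at a dominant gap and falls back", {
  model <- coarse_model(matrix(rnorm(9), 3, 3))
  pool <- structure_pool(rep(list(model), 1),
                         replicate(10, list(rigid_pose()),
                                   simplify = FALSE))
  pool$scores$gvm <- c(1, 1.1, 1.2, 1.25, 50, 51, 52, 53, 54, 55)
  expect_equal(pool_size(select_by_energy_gap(pool, 10)), 4)
  pool$scores$gvm <- seq(1, 10)
  expect_equal(pool_size(select_by_energy_gap(pool, 6)), 6)
})

test_that("scoring stage truncates, ranks by GVM, and enriches the top", {
  toy <- make_toy_assembly(one_ring_spec(seed = 77))
  ref <- toy$reference
  fine <- simulate_map(ref, 20)
  cfg <- gvm_config()
  cfg$model_scale <- calibrate_model_scale(ref, fine, cfg)
  pool <- make_decoy_pool(ref, 40, c(0.5, 25), seed = 9)
  pool$scores$total <- seq_len(40)          # fake assembly energies
  out <- scoring_stage(pool, fine, cfg, stage_plan(
    n_starts = 40, preassembly_keep = 40, scoring_keep = 30,
    refine_keep = 10))
  expect_equal(pool_size(out), 30)
  expect_false(is.unsorted(out$scores$gvm))
  # GVM enrichment: mean RMSD of the top 10 improves over the unsorted pool
  expect_lt(mean(out$scores$true_rmsd[1:10]),
            mean(pool$scores$true_rmsd[1:10]))
  expect_identical(scoring_stage(out, fine, cfg, stage_plan(
    n_starts = 40, preassembly_keep = 40, scoring_keep = 30,
    refine_keep = 10))$scores$gvm, out$scores$gvm)
})

test_that("swapped ring blocks score worse than the correct arrangement", {
  # asymmetric two-ring toy: swapping the rings must misfit the map
  spec <- toy_spec(rings = list(
    list(X = 5, radius = 24, Z = -18, n_beads = 10, spread = c(9, 5, 2)),
    list(X = 5, radius = 34, Z = 18, n_beads = 14, spread = c(14, 8, 2.5))),
    seed = 78)
  toy <- make_toy_assembly(spec)
  ref <- toy$reference
  fine <- simulate_map(ref, 20)
  cfg <- gvm_config()
  cfg$model_scale <- calibrate_model_scale(ref, fine, cfg)
  g_ok <- gvm_score(ref, fine, cfg)
  # swap ring blocks: ring 1 poses onto ring 2 components and vice versa
  # (components ordered ring by ring: 1-5 and 6-10)
  swapped <- ref
  swapped$poses <- ref$poses[c(6:10, 1:5)]
  g_bad <- gvm_score(swapped, fine, cfg)
  expect_gt(g_bad, g_ok)
})

test_that("a tiny end-to-end run is reproducible and improves the pool", {
  spec <- one_ring_spec(seed = 79)
  bench <- make_benchmark_case(spec)
  config <- list(
    starts = list(type = "ring", rings = lapply(bench$ring_specs, function(r) {
      r$radius <- 30; r$radius_jitter <- 6; r
    })),
    coarse_map = bench$coarse_map, fine_map = bench$fine_map,
    em_coarse = bench$em_coarse, em_fine = bench$em_fine,
    restraints = bench$restraints, gvm = bench$gvm,
    ff_params = pair_potential_params(),
    plan = small_plan(),
    symmetry_weight = bench$symmetry_weight,
    seed = 11,
    reference = bench$reference, equivalences = bench$equivalences)
  res1 <- run_protocol(config)
  expect_s3_class(res1, "em_protocol_result")
  expect_equal(pool_size(res1$pool), 3)
  expect_false(is.unsorted(res1$pool$scores$gvm))
  # stage counts non-increasing
  ns <- vapply(res1$stats, `[[`, 0, "n")
  expect_true(all(diff(ns) <= 0))
  res2 <- run_protocol(config)
  expect_equal(res1$rmsd_table, res2$rmsd_table, tolerance = 1e-12)
  expect_equal(res1$pool$scores$gvm, res2$pool$scores$gvm, tolerance = 1e-12)

  # JSON stage report
  rp <- tempfile(fileext = ".json")
  write_protocol_report(res1, rp)
  back <- jsonlite::read_json(rp)
  expect_equal(back$seed, 11)
  expect_true("refinement" %in% names(back$stages))
})

test_that("ranked models are written as PDB files with a score table", {
  toy <- make_toy_assembly(one_ring_spec(seed = 80))
  pool <- make_decoy_pool(toy$reference, 3, c(1, 5), seed = 12)
  dir <- tempfile()
  tab_path <- write_ranked_models(pool, dir, n = 2)
  expect_true(file.exists(file.path(dir, "model_001.pdb")))
  tab <- read.delim(tab_path)
  expect_equal(nrow(tab), 2)
  back <- read_pdb(file.path(dir, "model_001.pdb"))
  expect_equal(nrow(back$atom),
               nrow(assembly_coords(pool_assembly(pool, 1))$xyz))
})
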