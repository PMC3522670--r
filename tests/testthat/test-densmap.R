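test_that("sigma_from_resolution follows the half-resolution rule", {
  expect_equal(sigma_from_resolution(40), 20 / sqrt(3), tolerance = 1e-12)
  expect_equal(sigma_from_resolution(20), sigma_from_resolution(40) / 2)
  expect_error(sigma_from_resolution(0), "positive")
  expect_error(sigma_from_resolution(-5), "positive")
  # configurable divisor
  expect_equal(sigma_from_resolution(40, divisor = 1), 20)
})

test_that("simulate_map integrates bead weights and is linear", {
  m1 <- coarse_model(matrix(c(0, 0, 0), 1, 3), weight = 1)
  mp <- simulate_map(m1, 40, padding = 80)
  # total mass = sum * voxel volume
  expect_equal(sum(mp$values) * mp$voxel_size^3, 1, tolerance = 0.01)
  # global maximum at the bead position
  peak <- arrayInd(which.max(mp$values), dim(mp$values))
  world <- mp$origin + (peak - 1) * mp$voxel_size
  expect_true(all(abs(world - 0) <= mp$voxel_size / 2 + 1e-9))

  # linearity: two beads = sum of single-bead maps on shared geometry
  m2 <- coarse_model(rbind(c(0, 0, 0), c(12, 0, 0)), weight = c(2, 3))
  g <- simulate_map(m2, 40)
  ga <- simulate_map(coarse_model(matrix(c(0, 0, 0), 1, 3), weight = 2),
                     40, geometry = g)
  gb <- simulate_map(coarse_model(matrix(c(12, 0, 0), 1, 3), weight = 3),
                     40, geometry = g)
  expect_equal(g$values, ga$values + gb$values, tolerance = 1e-12)

  # equivariance: shifting the model by one voxel shifts the map one voxel
  gs <- simulate_map(coarse_model(matrix(c(g$voxel_size, 0, 0), 1, 3),
                                  weight = 2), 40, geometry = g)
  d <- dim(g$values)
  expect_equal(gs$values[2:d[1], , ], ga$values[1:(d[1] - 1), , ],
               tolerance = 1e-12)
  expect_error(simulate_map(m1, 40, voxel_size = -1), "positive")
})

test_that("downsample_join sums blocks and conserves density exactly", {
  g <- density_grid(array(1, c(4, 4, 4)), voxel_size = 2)
  d2 <- downsample_join(g, 2)
  expect_equal(dim(d2$values), c(2L, 2L, 2L))
  expect_true(all(d2$values == 8))
  expect_equal(d2$voxel_size, 4)
  expect_equal(sum(d2$values), sum(g$values))

  set.seed(6)
  g2 <- density_grid(array(runif(8^3), c(8, 8, 8)), voxel_size = 1.5)
  expect_equal(sum(downsample_join(g2, 2)$values), sum(g2$values))
  # factor 2 twice equals factor 4 once
  a <- downsample_join(downsample_join(g2, 2), 2)
  b <- downsample_join(g2, 4)
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_equal(a$origin, b$origin, tolerance = 1e-12)
  expect_error(downsample_join(g2, 1), "factor")
  # world coordinate of joined voxel centers is the block centroid
  expect_equal(d2$origin, g$origin + g$voxel_size / 2)
})

test_that("lowpass_filter blurs to the target width and conserves mass", {
  # delta spike -> Gaussian with the expected sigma (moment fit)
  d <- c(25, 25, 25)
  v <- array(0, d); v[13, 13, 13] <- 1
  g <- density_grid(v, voxel_size = 4, resolution = 16)
  f <- lowpass_filter(g, 40)
  s_expect <- sqrt(sigma_from_resolution(40)^2 - sigma_from_resolution(16)^2)
  xs <- (1:25 - 13) * 4
  prof <- apply(f$values, 1, sum)
  s_fit <- sqrt(sum(prof * xs^2) / sum(prof))
  expect_equal(s_fit, s_expect, tolerance = 0.02 * s_expect)
  expect_lt(abs(attr(f, "edge_loss")), 1e-3)

  # constant grid unchanged away from edges
  gc <- density_grid(array(2, d), voxel_size = 4, resolution = 16)
  fc <- lowpass_filter(gc, 30)
  expect_equal(fc$values[10:16, 10:16, 10:16],
               gc$values[10:16, 10:16, 10:16], tolerance = 1e-6)
  expect_error(lowpass_filter(g, 10), "coarser")

  # order-commutative with downsample_join on smooth inputs (within 1%)
  m <- tiny_model()
  sm <- simulate_map(m, 20, voxel_size = 5, padding = 50)
  a <- downsample_join(lowpass_filter(sm, 40), 2)
  b <- lowpass_filter(downsample_join(sm, 2), 40)
  rel <- max(abs(a$values - b$values)) / max(abs(b$values))
  expect_lt(rel, 0.01)
})

test_that("deconvolve approximately inverts a Gaussian blur", {
  m <- coarse_model(rbind(c(-6, 0, 0), c(6, 2, 0)), weight = c(2, 3))
  mp <- simulate_map(m, 24, voxel_size = 6, padding = 45)
  psf <- sigma_from_resolution(24)
  dec <- deconvolve(mp, psf)
  # re-blurring the deconvolved map recovers the input within 5% RMS
  reblur <- emassemble:::separable_convolve(
    dec$values, dec$voxel_size,
    function(off) exp(-off^2 / (2 * psf^2)) * dec$voxel_size /
      sqrt(2 * pi * psf^2))
  rel_rms <- sqrt(mean((reblur - mp$values)^2)) / sqrt(mean(mp$values^2))
  expect_lt(rel_rms, 0.05)

  # sigma -> 0 limit is the identity
  dec0 <- deconvolve(mp, 1e-9)
  expect_equal(dec0$values, mp$values, tolerance = 1e-6)
  expect_error(deconvolve(mp, -1), "sigma")

  # richardson-lucy route flags nonconvergence and returns its best iterate
  expect_warning(
    rl <- deconvolve(mp, psf, method = "richardson-lucy", iterations = 5),
    "did not converge")
  expect_false(attr(rl, "converged"))
})

test_that("rescale_to_sum scales linearly", {
  set.seed(7)
  g <- density_grid(array(runif(64), c(4, 4, 4)), voxel_size = 1)
  expect_equal(rescale_to_sum(g, sum(g$values))$values, g$values)
  expect_equal(rescale_to_sum(g, 2 * sum(g$values))$values, 2 * g$values)
  r <- rescale_to_sum(g, 12.5)
  expect_equal(sum(r$values), 12.5, tolerance = 1e-9)
  z <- density_grid(array(0, c(2, 2, 2)))
  expect_error(rescale_to_sum(z, 1), "zero-sum")
})

test_that("MRC and Situs map I/O round-trip", {
  set.seed(8)
  g <- density_grid(array(rnorm(5 * 6 * 7), c(5, 6, 7)),
                    origin = c(-3.5, 2.25, 10), voxel_size = 2.5)
  fm <- tempfile(fileext = ".mrc")
  write_map(g, fm)
  g2 <- read_map(fm)
  expect_equal(dim(g2$values), dim(g$values))
  expect_equal(g2$origin, g$origin, tolerance = 1e-5)
  expect_equal(g2$voxel_size, g$voxel_size, tolerance = 1e-6)
  expect_equal(g2$values, g$values, tolerance = 1e-6)   # float32

  fs <- tempfile(fileext = ".sit")
  write_map(g, fs)
  g3 <- read_map(fs)
  expect_equal(g3$values, g$values, tolerance = 1e-7)
  expect_equal(g3$origin, g$origin, tolerance = 1e-8)
  expect_equal(g3$voxel_size, g$voxel_size)

  # anisotropic-voxel MRC rejected: patch cella_y (header word 12)
  raw <- readBin(fm, "raw", file.size(fm))
  con <- rawConnection(raw, "r+")
  seek(con, 44)
  writeBin(99.0, con, size = 4, endian = "little")
  patched <- rawConnectionValue(con); close(con)
  fbad <- tempfile(fileext = ".mrc")
  writeBin(patched, fbad)
  expect_error(read_map(fbad), "nisotropic")
  expect_error(read_map(tempfile(fileext = ".xyz")), "guess")
})
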