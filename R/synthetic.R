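# Synthetic toy assemblies with known ground truth: rings of rigid
# anisotropic bead blobs (homo-oligomeric copies with distinguishable
# principal axes), their simulated maps, and labeled decoy pools. Every
# fixture is reproducible from (spec, seed); nothing is downloaded.

#' Toy assembly specification
#'
#' @param rings list of ring specs, each
#'   \code{list(X=, radius=, Z=, n_beads=, spread=)} where \code{spread}
#'   gives the curved-rod shape scales (Angstrom): half-length, bend depth
#'   and jitter; an optional \code{tilt} (degrees) sets the out-of-plane
#'   tilt of the rod axis. The default three-ring geometry is an axial
#'   stack of three well-separated sevenfold rings of distinguishable
#'   sizes (one smaller ring and two large rings), with subunits sized so
#'   neighbours within a ring stay resolvable at the 20 A scoring
#'   resolution.
#' @param seed generator seed.
#' @return list of class \code{toy_spec}.
#' @export
toy_spec <- function(rings = list(
                       list(X = 7, radius = 40, Z = -64.4, n_beads = 20,
                            spread = c(15, 8, 2.5)),
                       list(X = 7, radius = 46.0, Z = 0.0, n_beads = 24,
                            spread = c(17, 9, 3)),
                       list(X = 7, radius = 46.8, Z = 71.4, n_beads = 24,
                            spread = c(17, 9, 3))),
                     seed = 42) {
  for (r in rings) {
    if (r$X < 2) stop("ring subunit count must be >= 2")
    if (r$n_beads < 3) stop("need at least 3 beads per subunit")
    if (length(unique(r$spread)) < 2)
      stop("bead cloud must be non-spherical (orientation must be identifiable)")
  }
  structure(list(rings = rings, seed = seed), class = "toy_spec")
}

rotz <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Generate a toy reference assembly
#'
#' Each ring gets one randomly drawn anisotropic bead blob (weights in
#' pseudo-atom units of a few "atoms" per bead); the X copies are placed by
#' exact rotations about the z axis, so the reference has exact cyclic
#' positional symmetry per ring. Deterministic per spec seed.
#'
#' @param spec \code{\link{toy_spec}}.
#' @return list with \code{reference} (\code{assembly}), \code{models}
#'   (one \code{coarse_model} per ring), \code{rings} (the spec), and
#'   \code{equivalences} (component relabelings equivalent for RMSD:
#'   all combinations of per-ring cyclic shifts).
#' @export
make_toy_assembly <- function(spec = toy_spec()) {
  set.seed(spec$seed)
  models <- list()
  poses <- list()
  comp_models <- list()
  ci <- 0L
  for (ri in seq_along(spec$rings)) {
    r <- spec$rings[[ri]]
    nb <- r$n_beads
    # curved-rod bead cloud: half-length spread[1], bend depth spread[2],
    # Gaussian jitter spread[3]; the mass gradient along the rod makes the
    # two ends distinguishable, so orientation is identifiable at the
    # resolutions used
    t <- seq(-1, 1, length.out = nb)
    xyz <- cbind(r$spread[1] * t, r$spread[2] * (1 - t^2), 0) +
      matrix(rnorm(3 * nb, 0, r$spread[3]), nb, 3)
    xyz <- sweep(xyz, 2, colMeans(xyz))           # center the blob
    if (min(svd(xyz)$d) < 1e-6) stop("degenerate bead cloud")
    # weights sized so the assembled voxel atom density reaches the
    # standard protein-interior packing range (~14-18 per 10 A voxel)
    w <- seq(5, 10, length.out = nb)
    kind <- rep(c("CA", "SC"), length.out = nb)
    resi <- rep(seq_len(ceiling(nb / 2)), each = 2)[seq_len(nb)]
    model <- coarse_model(xyz, w, kind, resi,
                          name = paste0("ring", ri, "_subunit"))
    models[[ri]] <- model
    # base pose: subunit long axis tilted out of the ring plane (subunits
    # radiate, as in real oligomers, so neighbour densities stay distinct
    # and orientation is identifiable); bend points tangentially
    tilt <- if (is.null(r$tilt)) 30 * pi / 180
            else r$tilt * pi / 180
    ex <- c(cos(tilt), 0, sin(tilt))              # rod axis: radial + axial
    ey <- c(0, 1, 0)                              # bend: tangential
    ez <- c(-sin(tilt), 0, cos(tilt))
    R0 <- cbind(ex, ey, ez)
    t0 <- c(r$radius, 0, r$Z)
    for (k in seq_len(r$X)) {
      ci <- ci + 1L
      Rz <- rotz(2 * pi * (k - 1) / r$X)
      comp_models[[ci]] <- model
      poses[[ci]] <- rigid_pose(Rz %*% R0, as.numeric(Rz %*% t0))
    }
  }
  ref <- assembly(comp_models, poses)
  list(reference = ref, models = models, rings = spec$rings,
       equivalences = ring_equivalences(vapply(spec$rings, `[[`, 1, "X")))
}

#' Component relabelings equivalent under per-ring cyclic shifts
#'
#' @param X_per_ring integer vector of subunit counts per ring; components
#'   are assumed ordered ring by ring.
#' @return list of permutations of the component indices.
#' @export
ring_equivalences <- function(X_per_ring) {
  offs <- c(0L, cumsum(X_per_ring))
  shifts <- lapply(X_per_ring, function(X) seq_len(X) - 1L)
  grids <- expand.grid(shifts)
  out <- vector("list", nrow(grids))
  for (g in seq_len(nrow(grids))) {
    perm <- integer(0)
    for (ri in seq_along(X_per_ring)) {
      X <- X_per_ring[ri]; s <- grids[g, ri]
      perm <- c(perm, offs[ri] + ((seq_len(X) - 1L + s) %% X) + 1L)
    }
    out[[g]] <- perm
  }
  out
}

#' Generate a labeled decoy pool around a reference assembly
#'
#' Decoys are random rigid perturbations of every component (rotation about
#' the component COM plus translation), with magnitudes spanning the
#' requested unfitted-RMSD range; at least 5 percent of the decoys target
#' the lowest decile. Labels are the exactly computed unfitted RMSDs.
#'
#' @param reference \code{assembly}.
#' @param n number of decoys.
#' @param rmsd_range length-2 numeric (Angstrom).
#' @param seed master seed.
#' @return \code{structure_pool} with a \code{true_rmsd} score column.
#' @export
make_decoy_pool <- function(reference, n, rmsd_range = c(0, 30), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  lo <- rmsd_range[1]; hi <- rmsd_range[2]
  if (hi < lo) stop("unattainable rmsd range")
  nc <- length(reference$models)
  x0 <- lapply(seq_len(nc), function(i)
    apply_pose(reference$models[[i]], reference$poses[[i]]))
  wts <- lapply(reference$models, `[[`, "weight")
  coms <- lapply(seq_len(nc), function(i)
    colSums(x0[[i]] * wts[[i]]) / sum(wts[[i]]))
  rg <- vapply(seq_len(nc), function(i)
    radius_of_gyration(x0[[i]], wts[[i]]), 0)
  ref_xyz <- do.call(rbind, x0)
  nb <- vapply(x0, nrow, 1L)
  structures <- vector("list", n)
  labels <- numeric(n)
  # targeted magnitudes: a low-decile block plus an even span of the
  # range, in random order (labels must not correlate with pool position)
  set.seed(substream_seed(seed, 0))
  u <- c(runif(max(1, ceiling(0.08 * n)), 0.01, 0.1),
         seq(0.02, 1, length.out = n))[seq_len(n)]
  u <- sample(u)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i))
    m <- lo + (hi - lo) * u[i]
    poses <- vector("list", nc)
    xyz_new <- matrix(0, sum(nb), 3)
    row0 <- 0L
    disp2 <- 0
    for (ci in seq_len(nc)) {
      # rotation sized to contribute roughly half the displacement
      theta <- min(pi, 0.7 * m / max(rg[ci], 1))
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- rotation_from_axis_angle(ax * theta)
      xr <- sweep(sweep(x0[[ci]], 2, coms[[ci]]) %*% t(R), 2, coms[[ci]], "+")
      rot_rms2 <- mean(rowSums((xr - x0[[ci]])^2))
      tmag <- sqrt(max(0, m^2 - rot_rms2))
      tv <- rnorm(3); tv <- tv / sqrt(sum(tv^2)) * tmag
      xn <- sweep(xr, 2, tv, "+")
      xyz_new[row0 + seq_len(nb[ci]), ] <- xn
      row0 <- row0 + nb[ci]
      p0 <- reference$poses[[ci]]
      Rf <- R %*% p0$R
      tf <- as.numeric(R %*% (p0$t - coms[[ci]])) + coms[[ci]] + tv
      poses[[ci]] <- rigid_pose(Rf, tf)
    }
    structures[[i]] <- poses
    labels[i] <- rmsd(xyz_new, ref_xyz)
  }
  pool <- structure_pool(reference$models, structures)
  pool$scores$true_rmsd <- labels
  pool
}

#' Package a full synthetic benchmark case
#'
#' Generates the toy reference, simulates its maps at the given resolutions
#' (resolution-to-voxel ratio 4), builds the per-ring cyclic symmetry
#' restraints, calibrates the voxel-density caps and the intermolecular
#' spillover factor F on the reference (the same reference-inspection
#' procedure used for the original system), and calibrates the GVM model
#' scale.
#'
#' @param spec \code{\link{toy_spec}}.
#' @param resolutions coarse and fine resolution (Angstrom).
#' @return list with \code{reference}, \code{models}, \code{maps} (named by
#'   resolution), \code{coarse_map}, \code{fine_map}, \code{restraints},
#'   \code{em_coarse}, \code{em_fine}, \code{gvm}, \code{ring_specs} (for
#'   \code{\link{ring_topology_starts}}), and \code{equivalences}.
#' @export
make_benchmark_case <- function(spec = toy_spec(), resolutions = c(40, 20)) {
  toy <- make_toy_assembly(spec)
  ref <- toy$reference
  maps <- lapply(resolutions, function(res) simulate_map(ref, res))
  names(maps) <- as.character(resolutions)
  coarse_map <- maps[[which.max(resolutions)]]
  fine_map <- maps[[which.min(resolutions)]]

  # per-ring cyclic distance-equality restraints on the backbone beads
  offs <- c(0L, cumsum(vapply(toy$rings, `[[`, 1, "X")))
  restraints <- lapply(seq_along(toy$rings), function(ri) {
    m <- toy$models[[ri]]
    build_cx_restraints(sum(m$kind == "CA"), toy$rings[[ri]]$X,
                        components = offs[ri] + seq_len(toy$rings[[ri]]$X))
  })

  cal_cfg <- function(map, res, cap_factor) {
    src <- deconvolve(map, sigma_from_resolution(res))
    og <- precompute_overlap_grid(src, gaussian_params(res))
    tab <- max_overlap_table(ref, res, F = 1)
    Fcal <- calibrate_spillover(ref, og, tab)
    vg <- accumulate_voxel_density(ref, map)
    cap <- cap_factor * max(vg$values)
    emfit_config(res, F = Fcal, cap = cap)
  }
  res_c <- max(resolutions); res_f <- min(resolutions)
  em_coarse <- cal_cfg(coarse_map, res_c, 1.15)
  em_fine <- cal_cfg(fine_map, res_f, 1.0)

  gcfg <- gvm_config()
  gcfg$model_scale <- calibrate_model_scale(ref, fine_map, gcfg)

  # restraint-density calibration: the number of symmetry distance entries
  # grows linearly with the backbone bead count, and a protein-scale
  # monomer carries ~500 Calpha atoms; weighting the symmetry term by the
  # ratio restores protein-like ring stiffness for the sparse toy beads
  p_bb <- vapply(toy$models, function(m) sum(m$kind == "CA"), 0)
  sym_weight <- round(500 / mean(p_bb))

  ring_specs <- lapply(seq_along(toy$rings), function(ri) {
    r <- toy$rings[[ri]]
    list(model = toy$models[[ri]], X = r$X, Z = r$Z, radius = 35,
         radius_jitter = 15, z_jitter = 5)
  })
  list(reference = ref, models = toy$models, maps = maps,
       coarse_map = coarse_map, fine_map = fine_map,
       restraints = restraints, em_coarse = em_coarse, em_fine = em_fine,
       gvm = gcfg, ring_specs = ring_specs, symmetry_weight = sym_weight,
       equivalences = toy$equivalences)
}
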