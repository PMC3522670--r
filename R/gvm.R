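# Gradient vector matching: 3D Prewitt gradient fields of the density map
# and of the model's voxel atom density grid, compared with a significance
# threshold and a per-component tolerance. Used for ranking only (scoring),
# never as a force term.

#' GVM configuration
#'
#' @param significance_threshold voxels whose experimental gradient
#'   magnitude falls below this are ignored (default 2 units).
#' @param tolerance per-component deviation tolerated before the quadratic
#'   penalty starts (default 2; 20 for large full-complex runs where
#'   gradients are larger and more numerous).
#' @param model_scale multiplier applied to the model gradient; the
#'   atom-density gradients are systematically smaller than density-derived
#'   ones by a factor of about 1.35 (default; recalibrate with
#'   \code{\link{calibrate_model_scale}} for new systems).
#' @param penalty quadratic penalty constant (rankings are invariant to it).
#' @param significance \code{"norm"}: significance judged on the Euclidean
#'   norm of the experimental gradient (default); \code{"component"}:
#'   per-component.
#' @return list of class \code{gvm_config}.
#' @export
gvm_config <- function(significance_threshold = 2, tolerance = 2,
                       model_scale = 1.35, penalty = 1,
                       significance = c("norm", "component")) {
  stopifnot(significance_threshold >= 0, tolerance >= 0, model_scale > 0)
  structure(list(significance_threshold = significance_threshold,
                 tolerance = tolerance, model_scale = model_scale,
                 penalty = penalty,
                 significance = match.arg(significance)),
            class = "gvm_config")
}

shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx + dx; fy <- sy + dy; fz <- sz + dz
  ok_x <- fx >= 1 & fx <= d[1]; ok_y <- fy >= 1 & fy <= d[2]
  ok_z <- fz >= 1 & fz <= d[3]
  out[sx[ok_x], sy[ok_y], sz[ok_z]] <- a[fx[ok_x], fy[ok_y], fz[ok_z]]
  out
}

# fast single-axis +/-1 shifts via linear-index offsets; the wrapped
# boundary entries are zeroed with masks cached per grid geometry
.shift_masks <- new.env(parent = emptyenv())

axis_masks <- function(d) {
  key <- paste(d, collapse = "x")
  m <- .shift_masks[[key]]
  if (!is.null(m)) return(m)
  n <- prod(d)
  ix <- (seq_len(n) - 1L) %% d[1]
  iy <- ((seq_len(n) - 1L) %/% d[1]) %% d[2]
  iz <- (seq_len(n) - 1L) %/% (d[1] * d[2])
  m <- list(x_first = which(ix == 0L), x_last = which(ix == d[1] - 1L),
            y_first = which(iy == 0L), y_last = which(iy == d[2] - 1L),
            z_first = which(iz == 0L), z_last = which(iz == d[3] - 1L))
  .shift_masks[[key]] <- m
  m
}

# out[i] = a at the neighbour `dir` steps along `axis` (zeros outside)
shift_axis <- function(a, d, axis, dir, masks) {
  n <- length(a)
  step <- switch(axis, 1L, d[1], d[1] * d[2])
  out <- numeric(n)
  if (dir > 0) out[seq_len(n - step)] <- a[(step + 1L):n]
  else out[(step + 1L):n] <- a[seq_len(n - step)]
  zero <- switch(axis,
                 if (dir > 0) masks$x_last else masks$x_first,
                 if (dir > 0) masks$y_last else masks$y_first,
                 if (dir > 0) masks$z_last else masks$z_first)
  out[zero] <- 0
  out
}

# 3-point sum along one axis (value + both neighbours, zeros outside)
sum3_axis <- function(a, d, axis, masks) {
  a + shift_axis(a, d, axis, 1L, masks) + shift_axis(a, d, axis, -1L, masks)
}

#' 3D Prewitt gradient field of a grid
#'
#' The x component at a voxel is the sum over its 3x3 (y,z) neighbourhood of
#' the difference between the x+1 and x-1 planes (unnormalized Prewitt;
#' analogous for y and z). Boundary voxels, which lack the full 3x3x3
#' neighbourhood, are masked invalid.
#'
#' @param grid \code{density_grid} with dims >= 3 in each axis.
#' @return object of class \code{gradient_field}: arrays \code{Vx,Vy,Vz},
#'   logical \code{valid} mask and the grid geometry.
#' @export
prewitt_gradient <- function(grid) {
  v <- grid$values
  d <- dim(v)
  if (any(d < 3)) stop("grid too small for the Prewitt operator (need >= 3)")
  masks <- axis_masks(d)
  a <- as.numeric(v)
  sy <- sum3_axis(a, d, 2L, masks)
  sz <- sum3_axis(a, d, 3L, masks)
  box_yz <- sum3_axis(sz, d, 2L, masks)    # 3x3 box over (y,z)
  box_xz <- sum3_axis(sz, d, 1L, masks)
  box_xy <- sum3_axis(sy, d, 1L, masks)
  Vx <- shift_axis(box_yz, d, 1L, 1L, masks) -
        shift_axis(box_yz, d, 1L, -1L, masks)
  Vy <- shift_axis(box_xz, d, 2L, 1L, masks) -
        shift_axis(box_xz, d, 2L, -1L, masks)
  Vz <- shift_axis(box_xy, d, 3L, 1L, masks) -
        shift_axis(box_xy, d, 3L, -1L, masks)
  dim(Vx) <- d; dim(Vy) <- d; dim(Vz) <- d
  valid <- array(FALSE, d)
  valid[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  structure(list(Vx = Vx, Vy = Vy, Vz = Vz, valid = valid,
                 origin = grid$origin, voxel_size = grid$voxel_size,
                 dims = d),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  mags <- sqrt(x$Vx[x$valid]^2 + x$Vy[x$valid]^2 + x$Vz[x$valid]^2)
  cat("gradient_field ", paste(x$dims, collapse = "x"), ", |V| median ",
      signif(median(mags), 4), ", max ", signif(max(mags), 4), "\n", sep = "")
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(grid_geometry_of(a)$dims == grid_geometry_of(b)$dims) &&
    max(abs(grid_geometry_of(a)$origin - grid_geometry_of(b)$origin)) < tol &&
    abs(grid_geometry_of(a)$voxel_size - grid_geometry_of(b)$voxel_size) < tol
}

grid_geometry_of <- function(g) {
  if (inherits(g, "gradient_field"))
    list(origin = g$origin, voxel_size = g$voxel_size, dims = g$dims)
  else grid_geometry(g)
}

#' Model gradient field from a voxel atom density grid
#'
#' Prewitt gradient of the atom-density grid, multiplied by the systematic
#' model scale.
#'
#' @param vgrid voxel atom density \code{density_grid} on the experimental
#'   grid geometry (see \code{\link{accumulate_voxel_density}}).
#' @param scale model gradient scale (default 1.35).
#' @return \code{gradient_field}.
#' @export
model_gradient <- function(vgrid, scale = 1.35) {
  g <- prewitt_gradient(vgrid)
  g$Vx <- g$Vx * scale; g$Vy <- g$Vy * scale; g$Vz <- g$Vz * scale
  g
}

#' GVM mismatch energy between two gradient fields
#'
#' For every voxel where the experimental gradient is significant, each
#' Cartesian component of the deviation beyond the tolerance is penalized
#' quadratically:
#' \code{E = penalty * sum(max(0, |Vexp_d - Vmodel_d| - tol)^2)}.
#' Lower is better; the energy is deterministic.
#'
#' @param v_exp,v_model co-registered \code{gradient_field}s.
#' @param cfg \code{\link{gvm_config}}.
#' @return energy (scalar).
#' @export
gvm_energy <- function(v_exp, v_model, cfg = gvm_config()) {
  if (!same_geometry(v_exp, v_model)) stop("gradient fields not co-registered")
  valid <- v_exp$valid & v_model$valid
  if (cfg$significance == "norm") {
    mag2 <- v_exp$Vx^2 + v_exp$Vy^2 + v_exp$Vz^2
    sig <- valid & (mag2 >= cfg$significance_threshold^2)
    e <- 0
    for (comp in c("Vx", "Vy", "Vz")) {
      dev <- pmax(0, abs(v_exp[[comp]][sig] - v_model[[comp]][sig]) -
                    cfg$tolerance)
      e <- e + sum(dev^2)
    }
  } else {
    e <- 0
    for (comp in c("Vx", "Vy", "Vz")) {
      sig <- valid & (abs(v_exp[[comp]]) >= cfg$significance_threshold)
      dev <- pmax(0, abs(v_exp[[comp]][sig] - v_model[[comp]][sig]) -
                    cfg$tolerance)
      e <- e + sum(dev^2)
    }
  }
  cfg$penalty * e
}

#' Experimental reference gradient field for GVM scoring
#'
#' Rescales the map so its density sum equals the total model weight (the
#' unit convention under which voxel atom densities and map densities are
#' commensurate, mirroring the rescaling of experimental maps to the
#' simulated-map sum) and computes its Prewitt field.
#'
#' @param map \code{density_grid} at the scoring resolution.
#' @param total_weight summed bead weight of the assembly to be scored.
#' @return \code{gradient_field}.
#' @export
gvm_reference_field <- function(map, total_weight) {
  prewitt_gradient(rescale_to_sum(map, total_weight))
}

#' GVM energy of an assembly against a map
#'
#' Builds the assembly's voxel atom density on the map geometry, takes its
#' scaled Prewitt gradient and compares with the map's gradient field.
#'
#' @param asm \code{assembly}.
#' @param map \code{density_grid} at the scoring resolution.
#' @param cfg \code{\link{gvm_config}}.
#' @param v_exp optional precomputed \code{\link{gvm_reference_field}}
#'   (avoids recomputing it per assembly).
#' @return energy (scalar).
#' @export
gvm_score <- function(asm, map, cfg = gvm_config(), v_exp = NULL) {
  cc <- assembly_coords(asm)
  if (is.null(v_exp)) v_exp <- gvm_reference_field(map, sum(cc$weight))
  vg <- accumulate_voxel_density(cc, map)
  gvm_energy(v_exp, model_gradient(vg, cfg$model_scale), cfg)
}

#' Calibrate the model gradient scale on a reference structure
#'
#' Least-squares ratio between the experimental and the raw model gradients
#' over significant voxels; the value the default 1.35 plays for the
#' original system.
#'
#' @param reference reference \code{assembly}.
#' @param map scoring-resolution \code{density_grid}.
#' @param cfg \code{\link{gvm_config}} (its threshold defines significance).
#' @return scale factor to multiply model gradients by.
#' @export
calibrate_model_scale <- function(reference, map, cfg = gvm_config()) {
  cc <- assembly_coords(reference)
  v_exp <- gvm_reference_field(map, sum(cc$weight))
  v_mod <- prewitt_gradient(accumulate_voxel_density(cc, map))
  valid <- v_exp$valid
  mag2 <- v_exp$Vx^2 + v_exp$Vy^2 + v_exp$Vz^2
  sig <- valid & (mag2 >= cfg$significance_threshold^2)
  num <- sum(v_exp$Vx[sig] * v_mod$Vx[sig] + v_exp$Vy[sig] * v_mod$Vy[sig] +
               v_exp$Vz[sig] * v_mod$Vz[sig])
  den <- sum(v_mod$Vx[sig]^2 + v_mod$Vy[sig]^2 + v_mod$Vz[sig]^2)
  if (den == 0) stop("reference model gradient is zero over significant voxels")
  num / den
}

#' Rank a structure pool by GVM energy
#'
#' Scores every structure against the map and sorts the pool ascending by
#' GVM energy; ties are broken by prior rank (stable sort). The computed
#' energies are recorded in the pool's score table.
#'
#' @param pool \code{structure_pool}.
#' @param map scoring-resolution \code{density_grid}.
#' @param cfg \code{\link{gvm_config}}.
#' @return reordered \code{structure_pool}.
#' @export
rank_by_gvm <- function(pool, map, cfg = gvm_config()) {
  if (pool_size(pool) == 0) stop("empty pool")
  w_total <- sum(unlist(lapply(pool$models, `[[`, "weight")))
  v_exp <- gvm_reference_field(map, w_total)
  e <- vapply(seq_len(pool_size(pool)), function(i) {
    gvm_score(pool_assembly(pool, i), map, cfg, v_exp = v_exp)
  }, 0)
  pool$scores$gvm <- e
  pool_reorder(pool, order(e))
}

#' Score model files against a map and return a ranked table
#'
#' Reads each file as a coarse model (whitespace table via
#' \code{\link{read_coarse_model}}, or PDB via \code{\link{read_pdb}} +
#' \code{\link{coarse_grain}} for .pdb files), scores it with GVM and
#' returns the ranked table.
#'
#' @param files character vector of model files.
#' @param map \code{density_grid}.
#' @param cfg \code{\link{gvm_config}}.
#' @return data.frame with columns rank, file, gvm_energy.
#' @export
gvm_rank_files <- function(files, map, cfg = gvm_config()) {
  if (length(files) == 0) stop("no model files given")
  read_one <- function(f) {
    if (grepl("\\.pdb$", f, ignore.case = TRUE))
      coarse_grain(read_pdb(f), name = basename(f))
    else read_coarse_model(f)
  }
  e <- vapply(files, function(f) {
    m <- read_one(f)
    gvm_score(assembly(list(m)), map, cfg)
  }, 0)
  ord <- order(e)
  data.frame(rank = seq_along(files), file = files[ord],
             gvm_energy = e[ord], row.names = NULL)
}
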