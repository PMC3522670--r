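# Rigid-body energy minimization: quasi-Newton (BFGS with Armijo
# backtracking) over 6 degrees of freedom per unfrozen component
# (translation + incremental axis-angle rotation about the component COM),
# against any weighted stack of energy terms. Rotation gradients are exact
# via the left Jacobian of SO(3); translation and rotation coordinates are
# balanced by each component's radius of gyration.

#' Build an energy stack
#'
#' An energy stack is an ordered list of named, weighted energy terms. Each
#' term is a function taking the stacked coordinate list (as produced by
#' \code{\link{assembly_coords}}) and returning \code{list(energy, forces)}.
#' Use the \code{term_*} constructors for the built-in terms.
#'
#' @param ... terms created by \code{\link{term_em}},
#'   \code{\link{term_clash}}, \code{\link{term_symmetry}},
#'   \code{\link{term_location}}, \code{\link{term_gravity}},
#'   \code{\link{term_forcefield}}.
#' @return object of class \code{energy_stack}.
#' @export
energy_stack <- function(...) {
  terms <- list(...)
  if (length(terms) == 1 && is.list(terms[[1]]) &&
      !inherits(terms[[1]], "energy_term")) terms <- terms[[1]]
  if (length(terms) < 1) stop("energy stack needs at least one term")
  if (!all(vapply(terms, inherits, TRUE, "energy_term")))
    stop("all stack entries must be energy terms")
  nm <- vapply(terms, function(tm) tm$name, "")
  names(terms) <- make.unique(nm)
  structure(list(terms = terms), class = "energy_stack")
}

new_term <- function(name, weight, fn) {
  structure(list(name = name, weight = weight, fn = fn),
            class = "energy_term")
}

#' Energy term constructors
#'
#' Wrap the package's energy functions as stack terms with a stage weight.
#'
#' @param ogrid \code{overlap_grid} of the target map.
#' @param table \code{max_overlap_table}.
#' @param k_hard,k_soft hard/soft deficiency penalties.
#' @param weight stage weight of the term.
#' @return \code{energy_term}.
#' @export
term_em <- function(ogrid, table, k_hard = 100, k_soft = 1, weight = 1) {
  new_term("em_fit", weight, function(cc)
    em_fit_energy(cc, ogrid, table, k_hard, k_soft))
}

#' @rdname term_em
#' @param geometry grid geometry for voxel atom density.
#' @param cap per-voxel density cap.
#' @param k_clash clash penalty constant.
#' @export
term_clash <- function(geometry, cap, k_clash = 1, weight = 1) {
  geo <- grid_geometry(geometry)
  new_term("clash", weight, function(cc)
    clash_energy_fast(cc, geo, cap, k_clash))
}

# clash energy/forces without constructing the density_grid object
clash_energy_fast <- function(cc, geo, cap, k_clash) {
  tl <- trilinear_setup(geo$origin, geo$voxel_size, geo$dims, cc$xyz)
  vals <- numeric(prod(geo$dims))
  contrib <- tl$w * cc$weight
  if (any(!tl$inside)) contrib[!tl$inside, ] <- 0
  acc <- rowsum(as.numeric(contrib), as.integer(tl$idx))
  vals[as.integer(rownames(acc))] <- acc[, 1]
  excess <- vals - cap
  over <- excess > 0
  if (!any(over)) {
    return(list(energy = 0, forces = matrix(0, nrow(cc$xyz), 3)))
  }
  excess[!over] <- 0
  energy <- k_clash * sum(excess[over]^2)
  ec <- matrix(excess[tl$idx], nrow(tl$idx), 8)
  w2 <- -2 * k_clash * cc$weight
  forces <- cbind(w2 * .rowSums(ec * tl$dwx, nrow(ec), 8),
                  w2 * .rowSums(ec * tl$dwy, nrow(ec), 8),
                  w2 * .rowSums(ec * tl$dwz, nrow(ec), 8))
  if (any(!tl$inside)) forces[!tl$inside, ] <- 0
  list(energy = energy, forces = forces)
}

#' @rdname term_em
#' @param restraints symmetry / location restraints.
#' @param asm_template assembly whose layout the symmetry restraints index.
#' @export
term_symmetry <- function(restraints, asm_template, weight = 1) {
  pre <- precompute_symmetry_rows(asm_template, restraints)
  new_term("symmetry", weight, function(cc) symmetry_energy_fast(cc, pre))
}

#' @rdname term_em
#' @export
term_location <- function(restraints, weight = 1) {
  new_term("location", weight, function(cc) location_energy_cc(cc, restraints))
}

#' @rdname term_em
#' @param attract_k,repulse_radius,repulse_k see \code{\link{gravity_terms}}.
#' @export
term_gravity <- function(attract_k = 0.001, repulse_radius = NULL,
                         repulse_k = 1, weight = 1) {
  cache <- new.env(parent = emptyenv())
  new_term("gravity", weight, function(cc)
    gravity_fast(cc, attract_k, repulse_radius, repulse_k, cache))
}

# vectorized COM gravity; per-component weights/rows/radii cached (rigid
# components: radius of gyration is pose-invariant)
gravity_fast <- function(cc, attract_k, repulse_radius, repulse_k, cache) {
  nc <- max(cc$comp)
  n <- nrow(cc$xyz)
  if (nc < 2) return(list(energy = 0, forces = matrix(0, n, 3)))
  if (is.null(cache$rows)) {
    cache$rows <- split(seq_len(n), cc$comp)
    cache$W <- vapply(cache$rows, function(r) sum(cc$weight[r]), 0)
    cache$wfrac <- cc$weight / cache$W[cc$comp]
    rg <- vapply(seq_len(nc), function(j) {
      r <- cache$rows[[j]]
      radius_of_gyration(cc$xyz[r, , drop = FALSE], cc$weight[r])
    }, 0)
    pr <- which(upper.tri(diag(nc)), arr.ind = TRUE)
    cache$pa <- pr[, 1]; cache$pb <- pr[, 2]
    cache$r0 <- if (is.null(repulse_radius)) 0.8 * (rg[cache$pa] + rg[cache$pb])
                else rep(repulse_radius, length(cache$pa))
  }
  coms <- rowsum(cc$xyz * cc$weight, cc$comp, reorder = TRUE) / cache$W
  dv <- coms[cache$pb, , drop = FALSE] - coms[cache$pa, , drop = FALSE]
  r <- sqrt(.rowSums(dv^2, length(cache$pa), 3))
  r[r < 1e-12] <- 1e-12
  energy <- 0.5 * attract_k * sum(r^2)
  dEdr <- attract_k * r
  inr <- r < cache$r0
  if (any(inr)) {
    gap <- cache$r0[inr] - r[inr]
    energy <- energy + 0.5 * repulse_k * sum(gap^2)
    dEdr[inr] <- dEdr[inr] - repulse_k * gap
  }
  fpair <- (dEdr / r) * dv                      # force on a along +dv
  fcom <- rowsum(rbind(fpair, -fpair), c(cache$pa, cache$pb))
  forces <- fcom[cc$comp, , drop = FALSE] * cache$wfrac
  list(energy = energy, forces = forces)
}

#' @rdname term_em
#' @param params \code{pair_potential_params}.
#' @export
term_forcefield <- function(params, weight = 1) {
  cache <- new.env(parent = emptyenv())
  new_term("forcefield", weight, function(cc) {
    if (is.null(cache$pairs)) cache$pairs <- intercomponent_pairs(cc$comp)
    intermolecular_energy(cc, params, weight = 1, pairs = cache$pairs)
  })
}

#' Evaluate an energy stack on stacked coordinates
#'
#' @param stack \code{energy_stack}.
#' @param cc coordinate list (\code{\link{assembly_coords}}).
#' @return list with \code{energy}, \code{forces} and per-term
#'   \code{energies}.
#' @export
evaluate_stack <- function(stack, cc) {
  total <- 0
  forces <- matrix(0, nrow(cc$xyz), 3)
  energies <- numeric(length(stack$terms))
  names(energies) <- names(stack$terms)
  for (k in seq_along(stack$terms)) {
    tm <- stack$terms[[k]]
    if (tm$weight == 0) next
    r <- tm$fn(cc)
    if (!is.finite(r$energy))
      stop("energy term '", tm$name, "' returned a non-finite energy")
    energies[k] <- tm$weight * r$energy
    total <- total + tm$weight * r$energy
    forces <- forces + tm$weight * r$forces
  }
  list(energy = total, forces = forces, energies = energies)
}

#' Project per-bead forces onto rigid degrees of freedom
#'
#' @param forces n x 3 per-bead forces of one component.
#' @param xyz n x 3 bead positions.
#' @param weight bead weights (for the COM).
#' @return list with the net \code{force} and the net \code{torque} about
#'   the weighted center of mass.
#' @export
project_forces <- function(forces, xyz, weight = rep(1, nrow(xyz))) {
  com <- colSums(xyz * weight) / sum(weight)
  rel <- sweep(xyz, 2, com)
  torque <- c(sum(rel[, 2] * forces[, 3] - rel[, 3] * forces[, 2]),
              sum(rel[, 3] * forces[, 1] - rel[, 1] * forces[, 3]),
              sum(rel[, 1] * forces[, 2] - rel[, 2] * forces[, 1]))
  list(force = colSums(forces), torque = torque)
}

#' Rigid-body minimization of an assembly against an energy stack
#'
#' BFGS with backtracking line search over per-component translations and
#' incremental axis-angle rotations about the component COM. Accepted-step
#' energies are monotone non-increasing; rotations stay orthonormal (final
#' poses are re-projected onto SO(3), drift below 1e-9).
#'
#' @param asm starting \code{assembly}.
#' @param stack \code{energy_stack}.
#' @param options list: \code{max_iter} (500), \code{tol} (1e-6, stop when
#'   the accepted energy decrease falls below it), \code{frozen} (logical
#'   per component: fully frozen), \code{translations} (FALSE freezes all
#'   translations), \code{trace} (record per-term energies).
#' @return object of class \code{minimize_result}: \code{assembly},
#'   \code{energy}, \code{energies} (per term), \code{trace},
#'   \code{iterations}, \code{converged}.
#' @export
minimize <- function(asm, stack, options = list()) {
  opt <- modifyList(list(max_iter = 500, tol = 1e-6, frozen = NULL,
                         translations = TRUE, trace = FALSE), options)
  nc <- length(asm$models)
  frozen <- if (is.null(opt$frozen)) rep(FALSE, nc) else opt$frozen
  free <- which(!frozen)
  if (length(free) == 0) stop("all components frozen")
  use_t <- opt$translations

  # starting coordinates and rotation centers
  x0 <- lapply(seq_len(nc), function(i) apply_pose(asm$models[[i]],
                                                   asm$poses[[i]]))
  wts <- lapply(asm$models, `[[`, "weight")
  com0 <- lapply(seq_len(nc), function(i)
    colSums(x0[[i]] * wts[[i]]) / sum(wts[[i]]))
  x0c <- lapply(seq_len(nc), function(i) sub_rows(x0[[i]], com0[[i]]))
  xyz_base <- do.call(rbind, x0)
  L <- vapply(seq_len(nc), function(i)
    max(radius_of_gyration(x0[[i]], wts[[i]]), 1), 0)
  npar_c <- if (use_t) 6L else 3L
  npar <- npar_c * length(free)
  cc_template <- list(
    comp = rep(seq_len(nc), vapply(asm$models, n_beads, 1L)),
    weight = unlist(wts),
    kind = unlist(lapply(asm$models, `[[`, "kind")))
  rows_of <- split(seq_along(cc_template$comp), cc_template$comp)

  coords_at <- function(par) {
    xyz <- xyz_base
    for (m in seq_along(free)) {
      ci <- free[m]
      base <- (m - 1) * npar_c
      if (use_t) {
        t <- par[base + 1:3]; u <- par[base + 4:6]
      } else {
        t <- c(0, 0, 0); u <- par[base + 1:3]
      }
      R <- rotation_from_axis_angle(u / L[ci])
      xyz[rows_of[[ci]], ] <- add_rows(x0c[[ci]] %*% t(R), com0[[ci]] + t)
    }
    xyz
  }

  eval_at <- function(par) {
    xyz <- coords_at(par)
    cc <- cc_template; cc$xyz <- xyz
    ev <- evaluate_stack(stack, cc)
    grad <- numeric(npar)
    for (m in seq_along(free)) {
      ci <- free[m]
      base <- (m - 1) * npar_c
      rows <- rows_of[[ci]]
      f <- ev$forces[rows, , drop = FALSE]
      if (use_t) {
        u <- par[base + 4:6]
        tpar <- par[base + 1:3]
      } else {
        u <- par[base + 1:3]
        tpar <- c(0, 0, 0)
      }
      center <- com0[[ci]] + tpar
      rel <- sub_rows(xyz[rows, , drop = FALSE], center)
      tau <- c(sum(rel[, 2] * f[, 3] - rel[, 3] * f[, 2]),
               sum(rel[, 3] * f[, 1] - rel[, 1] * f[, 3]),
               sum(rel[, 1] * f[, 2] - rel[, 2] * f[, 1]))
      gw <- -as.numeric(crossprod(so3_left_jacobian(u / L[ci]), tau))
      if (use_t) {
        grad[base + 1:3] <- -colSums(f)
        grad[base + 4:6] <- gw / L[ci]
      } else {
        grad[base + 1:3] <- gw / L[ci]
      }
    }
    list(energy = ev$energy, grad = grad, energies = ev$energies)
  }

  par <- numeric(npar)
  cur <- eval_at(par)
  trace <- list(c(iter = 0, total = cur$energy, cur$energies))
  H <- diag(npar)
  first_update <- TRUE
  converged <- FALSE
  iter <- 0
  while (iter < opt$max_iter) {
    iter <- iter + 1
    d <- -as.numeric(H %*% cur$grad)
    slope <- sum(d * cur$grad)
    if (slope >= 0) { H <- diag(npar); d <- -cur$grad; slope <- sum(d * cur$grad) }
    if (sqrt(sum(cur$grad^2)) < 1e-12) { converged <- TRUE; break }
    alpha <- min(1, 2 / max(max(abs(d)), 1e-12))
    accepted <- FALSE
    for (ls in 1:30) {
      cand <- eval_at(par + alpha * d)
      if (is.finite(cand$energy) &&
          cand$energy <= cur$energy + 1e-4 * alpha * slope) {
        accepted <- TRUE; break
      }
      alpha <- alpha * 0.5
    }
    if (!accepted) { converged <- TRUE; break }
    s <- alpha * d
    y <- cand$grad - cur$grad
    sy <- sum(s * y)
    if (sy > 1e-12) {
      if (first_update) { H <- diag(npar) * (sy / sum(y * y)); first_update <- FALSE }
      Hy <- as.numeric(H %*% y)
      H <- H + ((sy + sum(y * Hy)) / sy^2) * tcrossprod(s) -
        (tcrossprod(Hy, s) + tcrossprod(s, Hy)) / sy
    }
    dE <- cur$energy - cand$energy
    par <- par + s
    cur <- cand
    trace[[length(trace) + 1]] <-
      c(iter = iter, total = cur$energy, cur$energies)
    if (dE < opt$tol) { converged <- TRUE; break }
  }

  # compose final poses, re-projected onto SO(3)
  poses <- asm$poses
  for (m in seq_along(free)) {
    ci <- free[m]
    base <- (m - 1) * npar_c
    tpar <- if (use_t) par[base + 1:3] else c(0, 0, 0)
    u <- if (use_t) par[base + 4:6] else par[base + 1:3]
    R <- orthonormalize(rotation_from_axis_angle(u / L[ci]))
    p0 <- asm$poses[[ci]]
    Rf <- orthonormalize(R %*% p0$R)
    tf <- as.numeric(R %*% (p0$t - com0[[ci]])) + com0[[ci]] + tpar
    poses[[ci]] <- rigid_pose(Rf, tf)
  }
  out <- assembly(asm$models, poses,
                  energy = as.list(c(total = cur$energy, cur$energies)))
  structure(list(assembly = out, energy = cur$energy,
                 energies = cur$energies,
                 trace = do.call(rbind, trace), iterations = iter,
                 converged = converged),
            class = "minimize_result")
}

orthonormalize <- function(R) {
  sv <- svd(R)
  Q <- sv$u %*% t(sv$v)
  if (det(Q) < 0) Q <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  Q
}

#' @export
print.minimize_result <- function(x, ...) {
  cat("minimize_result: E = ", signif(x$energy, 6), " after ", x$iterations,
      " iterations (", if (x$converged) "converged" else "max_iter", ")\n",
      sep = "")
  invisible(x)
}

#' Orientation-only minimization
#'
#' \code{\link{minimize}} with all translations frozen: positions stay
#' fixed, only component orientations move.
#'
#' @param asm,stack,options as in \code{\link{minimize}}.
#' @return \code{minimize_result}.
#' @export
orientation_only_minimize <- function(asm, stack, options = list()) {
  options$translations <- FALSE
  minimize(asm, stack, options)
}

# ---- coordinate-list versions of the restraint energies --------------------
# (avoid rebuilding assemblies inside minimization inner loops)

# Precompute the global bead rows each symmetry entry touches, so the
# per-evaluation work is pure vector arithmetic.
precompute_symmetry_rows <- function(asm_template, restraints) {
  if (inherits(restraints, "symmetry_restraints")) restraints <- list(restraints)
  offs <- c(0L, cumsum(vapply(asm_template$models, n_beads, 1L)))
  bbidx <- lapply(seq_along(asm_template$models), function(i) {
    offs[i] + which(asm_template$models[[i]]$kind == "CA")
  })
  lapply(restraints, function(rs) {
    comp <- rs$components
    if (max(comp) > length(asm_template$models))
      stop("restraint component index out of range")
    e <- rs$entries
    rowA <- vapply(seq_len(nrow(e)),
                   function(r) bbidx[[comp[e$j1[r]]]][e$a[r]], 1L)
    rowB <- vapply(seq_len(nrow(e)),
                   function(r) bbidx[[comp[e$j2[r]]]][e$b[r]], 1L)
    if (anyNA(rowA) || anyNA(rowB))
      stop("assembly monomers have fewer backbone beads than the restraints")
    # entries come in contiguous equal-size blocks, one per equality set
    bs <- as.integer(table(e$set)[1])
    ns <- length(rowA) %/% bs
    stopifnot(all(e$set == rep(seq_len(ns), each = bs)))
    list(rowA = rowA, rowB = rowB, bs = bs, ns = ns, c = rs$c,
         rows = c(rowB, rowA))
  })
}

symmetry_energy_fast <- function(cc, pre) {
  forces <- matrix(0, nrow(cc$xyz), 3)
  energy <- 0
  for (ps in pre) {
    dvec <- cc$xyz[ps$rowB, , drop = FALSE] - cc$xyz[ps$rowA, , drop = FALSE]
    dist <- sqrt(.rowSums(dvec^2, length(ps$rowA), 3))
    D <- dist - rep(.colMeans(dist, ps$bs, ps$ns), each = ps$bs)
    energy <- energy + 0.5 * ps$c * sum(D * D)
    fB <- (-ps$c * D / pmax(dist, 1e-12)) * dvec
    acc <- rowsum(rbind(fB, -fB), ps$rows)
    ridx <- as.integer(rownames(acc))
    forces[ridx, ] <- forces[ridx, ] + acc
  }
  list(energy = energy, forces = forces)
}

location_energy_cc <- function(cc, restraints) {
  if (inherits(restraints, "location_restraint")) restraints <- list(restraints)
  forces <- matrix(0, nrow(cc$xyz), 3)
  energy <- 0
  for (lr in restraints) {
    rows <- which(cc$comp == lr$component)
    if (length(rows) == 0) stop("invalid component index ", lr$component)
    w <- cc$weight[rows]; W <- sum(w)
    com <- colSums(cc$xyz[rows, , drop = FALSE] * w) / W
    d <- com - lr$target
    energy <- energy + 0.5 * lr$k * sum(d^2)
    forces[rows, ] <- forces[rows, ] + tcrossprod(w / W, -lr$k * d)
  }
  list(energy = energy, forces = forces)
}

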