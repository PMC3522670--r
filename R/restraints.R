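# Symmetry distance-equality restraints (C_X and D_4), location restraints
# and the pre-assembly center-of-mass "gravity" terms. Symmetry is enforced
# purely through distance equalities between backbone beads, so no symmetry
# axis is ever defined and the energy is invariant under global rigid
# transforms of the assembly.

#' Build cyclic (C_X) symmetry distance-equality restraints
#'
#' Backbone beads are arranged into pairs (A = bead i, B = bead p-i, for
#' i <= p-i); for each pair, equality set S_k (k = 1..floor(X/2)) holds the
#' X cyclically shifted distances d(A_n, B_(n+k)), n = 1..X with monomer
#' indices modulo X. Every distance in a set is restrained toward the set
#' mean. For X = 7 this yields the three equalities S1, S2, S3 with 7
#' distances each per pair.
#'
#' @param p number of backbone beads per monomer (>= 1).
#' @param X symmetry order (>= 2).
#' @param c harmonic force constant (kcal/mol/A; default 0.005).
#' @param components optional integer vector (length X) mapping ring
#'   positions to assembly component indices (default 1:X).
#' @return object of class \code{symmetry_restraints}.
#' @export
build_cx_restraints <- function(p, X, c = 0.005, components = seq_len(X)) {
  if (X < 2) stop("symmetry order X must be >= 2")
  if (p < 1) stop("need at least one backbone bead")
  if (length(components) != X) stop("components must have length X")
  # bead i pairs with bead p-i+1; an odd p leaves a middle self-pair
  ii <- seq_len((p + 1L) %/% 2L)
  kk <- seq_len(floor(X / 2))
  n <- seq_len(X)
  ent <- list(); set_id <- 0L
  for (i in ii) {
    for (k in kk) {
      set_id <- set_id + 1L
      ent[[set_id]] <- data.frame(
        set = set_id, j1 = n, a = i,
        j2 = ((n + k - 1L) %% X) + 1L, b = p - i + 1L)
    }
  }
  entries <- do.call(rbind, ent)
  structure(list(order = X, entries = entries, c = c,
                 components = as.integer(components), p = p,
                 type = "cyclic"),
            class = "symmetry_restraints")
}

#' Build D4 symmetry distance-equality restraints
#'
#' For a tetramer, each backbone-bead pair (A = bead i, B = bead p-i) gets
#' the three 2-member equalities d(A1,B2) = d(A3,B4); d(A1,B3) = d(A2,B4);
#' d(A1,B4) = d(A2,B3).
#'
#' @param p number of backbone beads per monomer.
#' @param c force constant (kcal/mol/A).
#' @param components component indices of the four monomers.
#' @return \code{symmetry_restraints}.
#' @export
build_d4_restraints <- function(p, c = 0.005, components = 1:4) {
  if (length(components) != 4) stop("D4 restraints need exactly 4 monomers")
  if (p < 1) stop("need at least one backbone bead")
  ii <- seq_len((p + 1L) %/% 2L)
  eqs <- list(rbind(c(1, 2), c(3, 4)),
              rbind(c(1, 3), c(2, 4)),
              rbind(c(1, 4), c(2, 3)))
  ent <- list(); set_id <- 0L
  for (i in ii) {
    for (q in eqs) {
      set_id <- set_id + 1L
      ent[[set_id]] <- data.frame(set = set_id, j1 = q[, 1], a = i,
                                  j2 = q[, 2], b = p - i + 1L)
    }
  }
  structure(list(order = 4L, entries = do.call(rbind, ent), c = c,
                 components = as.integer(components), p = p,
                 type = "dihedral"),
            class = "symmetry_restraints")
}

#' Write / read symmetry restraints as a text file
#'
#' Header lines (key value) carry the type, order, force constant and
#' component mapping; the body is the whitespace-delimited entry table
#' (set j1 a j2 b).
#'
#' @param restraints \code{symmetry_restraints}.
#' @param path file path.
#' @export
write_restraints <- function(restraints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# type", restraints$type),
               paste("# order", restraints$order),
               paste("# c", restraints$c),
               paste("# p", restraints$p),
               paste("# components",
                     paste(restraints$components, collapse = " "))), con)
  write.table(restraints$entries, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  hdr <- readLines(path, n = 5)
  val <- function(key) sub(paste0("# ", key, " "), "", grep(
    paste0("^# ", key, " "), hdr, value = TRUE))
  entries <- read.table(path, header = TRUE, comment.char = "#")
  structure(list(order = as.integer(val("order")), entries = entries,
                 c = as.numeric(val("c")),
                 components = as.integer(strsplit(val("components"),
                                                  " ")[[1]]),
                 p = as.integer(val("p")), type = val("type")),
            class = "symmetry_restraints")
}

#' @export
print.symmetry_restraints <- function(x, ...) {
  cat("symmetry_restraints (", x$type, "): order ", x$order, ", ",
      max(x$entries$set), " equality sets, ", nrow(x$entries),
      " distances, c = ", x$c, "\n", sep = "")
  invisible(x)
}

# backbone-bead world coordinates per component, as a list of matrices
backbone_coords <- function(asm) {
  lapply(seq_along(asm$models), function(i) {
    m <- asm$models[[i]]
    apply_pose(m, asm$poses[[i]])[m$kind == "CA", , drop = FALSE]
  })
}

# row offset of each component's beads in the stacked coordinate matrix
bead_offsets <- function(asm) {
  n <- vapply(asm$models, n_beads, 1L)
  c(0L, cumsum(n))[seq_along(n)]
}

#' Symmetry restraint energy and forces
#'
#' For each equality set the mean distance is computed; each entry's
#' deviation D from the mean is restrained with force F = -c*D along the
#' pair axis and energy c*D^2/2 (the integral of the restoring force).
#'
#' @param asm \code{assembly}.
#' @param restraints a \code{symmetry_restraints} object or a list of them
#'   (e.g. one per ring).
#' @return list with \code{energy} and \code{forces} (one row per assembly
#'   bead; forces sum to zero).
#' @export
symmetry_energy <- function(asm, restraints) {
  if (inherits(restraints, "symmetry_restraints"))
    restraints <- list(restraints)
  cc <- assembly_coords(asm)
  forces <- matrix(0, nrow(cc$xyz), 3)
  offs <- bead_offsets(asm)
  # global row index of the a-th backbone bead of component comp
  bbidx <- lapply(seq_along(asm$models), function(i) {
    offs[i] + which(asm$models[[i]]$kind == "CA")
  })
  energy <- 0
  for (rs in restraints) {
    comp <- rs$components
    if (max(comp) > length(asm$models))
      stop("restraint component index out of range")
    p_avail <- vapply(bbidx[comp], length, 1L)
    if (any(p_avail < rs$p))
      stop("assembly monomers have fewer backbone beads than the restraints")
    e <- rs$entries
    rowA <- vapply(seq_len(nrow(e)),
                   function(r) bbidx[[comp[e$j1[r]]]][e$a[r]], 1L)
    rowB <- vapply(seq_len(nrow(e)),
                   function(r) bbidx[[comp[e$j2[r]]]][e$b[r]], 1L)
    dvec <- cc$xyz[rowB, , drop = FALSE] - cc$xyz[rowA, , drop = FALSE]
    dist <- sqrt(rowSums(dvec^2))
    mean_d <- ave(dist, e$set)
    D <- dist - mean_d
    energy <- energy + 0.5 * rs$c * sum(D^2)
    # dE/d(dist_entry) = c * D (the set-mean coupling cancels: sum D = 0)
    u <- dvec / pmax(dist, 1e-12)
    fB <- -rs$c * D * u
    acc <- rowsum(rbind(fB, -fB), c(rowB, rowA))
    ridx <- as.integer(rownames(acc))
    forces[ridx, ] <- forces[ridx, ] + acc
  }
  list(energy = energy, forces = forces)
}

#' Location restraints
#'
#' Harmonic restraints on component centers of mass:
#' E = k/2 |com - target|^2, force -k*(com - target) applied at the COM and
#' distributed over the component's beads in proportion to their weights.
#'
#' @param component component index.
#' @param target length-3 target position (Angstrom).
#' @param k force constant (kcal/mol/A; default 0.5).
#' @return object of class \code{location_restraint}.
#' @export
location_restraint <- function(component, target, k = 0.5) {
  stopifnot(length(target) == 3, k > 0)
  structure(list(component = as.integer(component),
                 target = as.numeric(target), k = k),
            class = "location_restraint")
}

#' @rdname location_restraint
#' @param asm \code{assembly}.
#' @param restraints list of \code{location_restraint}s.
#' @return for \code{location_energy}: list with \code{energy} and
#'   \code{forces}.
#' @export
location_energy <- function(asm, restraints) {
  cc <- if (inherits(asm, "assembly")) assembly_coords(asm) else asm
  location_energy_cc(cc, restraints)
}

#' Center-of-mass gravity terms
#'
#' Pre-assembly device: a weak, long-range harmonic attraction between all
#' component center-of-mass pairs (E = attract_k/2 r^2) plus a strong,
#' short-range harmonic repulsion inside \code{repulse_radius}
#' (E = repulse_k/2 (r0 - r)^2 for r < r0). Forces act on the COMs and are
#' distributed weight-proportionally over beads; pair forces are equal and
#' opposite, so total momentum is conserved.
#'
#' @param asm \code{assembly} with >= 2 components.
#' @param attract_k attraction constant (kcal/mol/A^2; default 0.001).
#' @param repulse_radius repulsion onset distance r0; default 0.8 times the
#'   sum of the two components' radii of gyration.
#' @param repulse_k repulsion constant (default 1).
#' @return list with \code{energy} and \code{forces}.
#' @export
gravity_terms <- function(asm, attract_k = 0.001, repulse_radius = NULL,
                          repulse_k = 1) {
  cc <- if (inherits(asm, "assembly")) assembly_coords(asm) else asm
  gravity_fast(cc, attract_k, repulse_radius, repulse_k,
               new.env(parent = emptyenv()))
}
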