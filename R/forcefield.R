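# Coarse-grained intermolecular pair potential used in the refinement
# stages: a soft 8-6 potential per bead-kind pair with smooth switching at
# a cutoff, plus an optional screened Coulomb term. Only inter-component
# pairs interact (components are rigid).

#' Pair potential parameters
#'
#' The 8-6 potential \code{U(r) = depth*(3*(rm/r)^8 - 4*(rm/r)^6)} has its
#' minimum \code{-depth} at \code{r = rm}, with \code{rm} the sum of the two
#' beads' radii and \code{depth} the geometric mean of their well depths.
#'
#' @param kinds bead kind labels the table covers.
#' @param radius per-kind radius (Angstrom, > 0).
#' @param depth per-kind well depth (kcal/mol, >= 0).
#' @param charge per-kind charge (e; 0 disables electrostatics).
#' @param dielectric relative dielectric for the Coulomb term.
#' @param cutoff pair cutoff (Angstrom).
#' @param switch_start onset of the switching function (Angstrom).
#' @return object of class \code{pair_potential_params}.
#' @export
pair_potential_params <- function(kinds = c("CA", "SC"),
                                  radius = c(2.0, 2.2),
                                  depth = c(0.05, 0.05),
                                  charge = c(0, 0),
                                  dielectric = 15,
                                  cutoff = 15, switch_start = 12) {
  stopifnot(length(radius) == length(kinds), all(radius > 0),
            length(depth) == length(kinds), all(depth >= 0),
            length(charge) == length(kinds),
            cutoff > switch_start, switch_start > 0)
  structure(list(kinds = kinds, radius = setNames(radius, kinds),
                 depth = setNames(depth, kinds),
                 charge = setNames(charge, kinds),
                 dielectric = dielectric, cutoff = cutoff,
                 switch_start = switch_start),
            class = "pair_potential_params")
}

#' Read/write a pair potential parameter table
#'
#' Whitespace-delimited columns: kind radius depth charge.
#' @param params \code{pair_potential_params}.
#' @param path file path.
#' @export
write_pair_params <- function(params, path) {
  df <- data.frame(kind = params$kinds, radius = params$radius,
                   depth = params$depth, charge = params$charge)
  write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pair_params
#' @param dielectric,cutoff,switch_start as in
#'   \code{\link{pair_potential_params}}.
#' @export
read_pair_params <- function(path, dielectric = 15, cutoff = 15,
                             switch_start = 12) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  pair_potential_params(df$kind, df$radius, df$depth, df$charge,
                        dielectric, cutoff, switch_start)
}

intercomponent_pairs <- function(comp) {
  n <- length(comp)
  idx <- which(outer(comp, comp, "!=") & upper.tri(diag(n)), arr.ind = TRUE)
  unname(idx)
}

# CHARMM-style switching function on [rs, rc] and its derivative
switch_fun <- function(r, rs, rc) {
  s <- rep(1, length(r))
  ds <- rep(0, length(r))
  mid <- r > rs & r < rc
  off <- r >= rc
  if (any(mid)) {
    rm2 <- r[mid]^2; rc2 <- rc^2; rs2 <- rs^2
    den <- (rc2 - rs2)^3
    s[mid] <- (rc2 - rm2)^2 * (rc2 + 2 * rm2 - 3 * rs2) / den
    ds[mid] <- (2 * (rc2 - rm2) * (-2 * r[mid]) * (rc2 + 2 * rm2 - 3 * rs2) +
                  (rc2 - rm2)^2 * 4 * r[mid]) / den
  }
  s[off] <- 0
  list(s = s, ds = ds)
}

#' Intermolecular force-field energy and forces
#'
#' Sum over all inter-component bead pairs within the cutoff of the
#' switched 8-6 potential (plus screened Coulomb when charges are set),
#' scaled by the stage weight. Analytic pairwise forces are equal and
#' opposite.
#'
#' @param asm \code{assembly} or coordinate list.
#' @param params \code{\link{pair_potential_params}} covering every bead
#'   kind in the assembly.
#' @param weight stage weight multiplying energy and forces (e.g. 0.01 in
#'   early refinement).
#' @param pairs optional precomputed 2-column matrix of inter-component
#'   bead pairs (avoids re-enumerating them in inner loops).
#' @return list with \code{energy} and \code{forces}.
#' @export
intermolecular_energy <- function(asm, params, weight = 1, pairs = NULL) {
  cc <- if (inherits(asm, "assembly")) assembly_coords(asm) else asm
  n <- nrow(cc$xyz)
  forces <- matrix(0, n, 3)
  if (weight == 0) return(list(energy = 0, forces = forces))
  miss <- setdiff(unique(cc$kind), params$kinds)
  if (length(miss) > 0)
    stop("no pair parameters for bead kind(s): ", paste(miss, collapse = ", "))
  if (is.null(pairs)) pairs <- intercomponent_pairs(cc$comp)
  i <- pairs[, 1]; j <- pairs[, 2]
  dv <- cc$xyz[j, , drop = FALSE] - cc$xyz[i, , drop = FALSE]
  r2 <- rowSums(dv^2)
  keep <- r2 < params$cutoff^2
  if (!any(keep)) return(list(energy = 0, forces = forces))
  i <- i[keep]; j <- j[keep]; dv <- dv[keep, , drop = FALSE]
  r <- sqrt(r2[keep])
  rm_ <- params$radius[cc$kind[i]] + params$radius[cc$kind[j]]
  eps <- sqrt(params$depth[cc$kind[i]] * params$depth[cc$kind[j]])
  x6 <- (rm_ / r)^6
  x8 <- x6 * (rm_ / r)^2
  u <- eps * (3 * x8 - 4 * x6)
  dudr <- eps * (-24 * x8 + 24 * x6) / r
  qq <- params$charge[cc$kind[i]] * params$charge[cc$kind[j]]
  if (any(qq != 0)) {
    ke <- 332.0636 / params$dielectric
    u <- u + ke * qq / r
    dudr <- dudr - ke * qq / r^2
  }
  sw <- switch_fun(r, params$switch_start, params$cutoff)
  e_pair <- u * sw$s
  dEdr <- dudr * sw$s + u * sw$ds
  energy <- weight * sum(e_pair)
  # force on j = -dE/dx_j = -dEdr * u_ij (u_ij unit vector i -> j)
  fj <- -weight * (dEdr / r) * dv
  acc <- rowsum(rbind(fj, -fj), c(j, i))
  ridx <- as.integer(rownames(acc))
  forces[ridx, ] <- forces[ridx, ] + acc
  list(energy = energy, forces = forces)
}
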