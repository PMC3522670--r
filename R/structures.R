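#' @importFrom stats runif rnorm quantile median sd cor fft setNames ave
#' @importFrom utils head tail read.table write.table modifyList
#' @importFrom graphics plot
NULL

# ---- rotation / pose primitives -------------------------------------------

#' Rotation matrix from an axis-angle vector (Rodrigues formula)
#'
#' @param w numeric length-3 axis-angle vector; its norm is the rotation
#'   angle in radians, its direction the rotation axis.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_from_axis_angle <- function(w) {
  stopifnot(length(w) == 3, all(is.finite(w)))
  theta <- sqrt(sum(w^2))
  if (theta < 1e-12) {
    K <- skew3(w)
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  k <- w / theta
  K <- skew3(k)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# Left Jacobian of SO(3): exp((w + dw)^) = exp((J_l(w) dw)^) exp(w^).
# Needed for exact gradients of an energy w.r.t. an axis-angle parameter.
so3_left_jacobian <- function(w) {
  theta <- sqrt(sum(w^2))
  K <- skew3(w)
  if (theta < 1e-6) {
    return(diag(3) + 0.5 * K + (K %*% K) / 6)
  }
  diag(3) + ((1 - cos(theta)) / theta^2) * K +
    ((theta - sin(theta)) / theta^3) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

#' Construct a rigid pose (rotation + translation)
#'
#' A pose maps model-frame coordinates x to world coordinates
#' \code{R \%*\% x + t}.
#'
#' @param R 3x3 proper rotation matrix (orthonormal within 1e-8).
#' @param t numeric length-3 translation in Angstrom.
#' @return object of class \code{rigid_pose}.
#' @export
rigid_pose <- function(R = diag(3), t = c(0, 0, 0)) {
  if (!is_rotation(R))
    stop("R must be a proper rotation matrix (orthonormal, det +1)")
  stopifnot(length(t) == 3, all(is.finite(t)))
  structure(list(R = R, t = as.numeric(t)), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("rigid_pose: t = (", paste(signif(x$t, 4), collapse = ", "),
      "), angle = ", signif(rotation_angle(x$R) * 180 / pi, 4), " deg\n",
      sep = "")
  invisible(x)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Compose two rigid poses
#'
#' \code{pose_compose(p, q)} is the pose that first applies \code{q}, then
#' \code{p}; composition is associative.
#' @param p,q \code{rigid_pose} objects.
#' @return \code{rigid_pose}.
#' @export
pose_compose <- function(p, q) {
  rigid_pose(p$R %*% q$R, as.numeric(p$R %*% q$t) + p$t)
}

#' @rdname pose_compose
#' @export
pose_inverse <- function(p) {
  rigid_pose(t(p$R), as.numeric(-t(p$R) %*% p$t))
}

#' Uniformly random rotation matrix
#'
#' Draws from the Haar measure on SO(3) via normalized quaternions.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# ---- coarse model ----------------------------------------------------------

#' Construct a coarse-grained bead model
#'
#' A subunit represented as beads: positions in a reference frame, positive
#' mass-like weights, a backbone/sidechain kind label and a residue index per
#' bead. Backbone beads ("CA") are what the symmetry restraints pair up.
#'
#' @param xyz n x 3 numeric matrix of bead positions (Angstrom).
#' @param weight length-n positive weights.
#' @param kind length-n character, \code{"CA"} (backbone) or \code{"SC"}
#'   (sidechain).
#' @param residue length-n integer residue index.
#' @param name model name.
#' @return object of class \code{coarse_model}.
#' @export
coarse_model <- function(xyz, weight = rep(1, nrow(xyz)),
                         kind = rep("CA", nrow(xyz)),
                         residue = seq_len(nrow(xyz)),
                         name = "model") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 || nrow(xyz) < 1) stop("xyz must be an n x 3 matrix, n >= 1")
  if (!all(is.finite(xyz))) stop("bead positions must be finite")
  if (length(weight) != nrow(xyz) || any(!is.finite(weight) | weight <= 0))
    stop("weights must be positive and finite, one per bead")
  if (length(kind) != nrow(xyz) || !all(kind %in% c("CA", "SC")))
    stop("kind must be 'CA' or 'SC', one per bead")
  res <- as.integer(residue)
  # every residue needs a backbone bead (symmetry pairing relies on it)
  if (!all(unique(res) %in% res[kind == "CA"]))
    stop("every residue must have a backbone ('CA') bead")
  structure(list(xyz = unname(xyz), weight = as.numeric(weight),
                 kind = kind, residue = res, name = name),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat("coarse_model '", x$name, "': ", nrow(x$xyz), " beads (",
      sum(x$kind == "CA"), " backbone), total weight ",
      signif(sum(x$weight), 6), "\n", sep = "")
  invisible(x)
}

n_beads <- function(model) nrow(model$xyz)

model_com <- function(model) {
  colSums(model$xyz * model$weight) / sum(model$weight)
}

radius_of_gyration <- function(xyz, weight = rep(1, nrow(xyz))) {
  com <- colSums(xyz * weight) / sum(weight)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(weight * d2) / sum(weight))
}

#' Apply a rigid pose to a coarse model
#'
#' @param model \code{coarse_model}.
#' @param pose \code{rigid_pose}.
#' @return n x 3 matrix of placed coordinates \code{x' = R x + t}.
#' @export
apply_pose <- function(model, pose) {
  if (!inherits(pose, "rigid_pose")) pose <- rigid_pose(pose$R, pose$t)
  transform_xyz(model$xyz, pose)
}

transform_xyz <- function(xyz, pose) {
  add_rows(xyz %*% t(pose$R), pose$t)
}

# fast row-wise add/subtract of a length-3 vector (avoids sweep overhead)
add_rows <- function(x, v) x + rep(v, each = nrow(x))
sub_rows <- function(x, v) x - rep(v, each = nrow(x))

# ---- assembly --------------------------------------------------------------

#' Construct an assembly of posed components
#'
#' @param models list of \code{coarse_model}, one per component.
#' @param poses list of \code{rigid_pose}, same length.
#' @param energy optional named list of per-term energies.
#' @return object of class \code{assembly}.
#' @export
assembly <- function(models, poses = NULL, energy = NULL) {
  if (length(models) < 1) stop("assembly needs at least one component")
  if (is.null(poses)) poses <- replicate(length(models), rigid_pose(),
                                         simplify = FALSE)
  if (length(poses) != length(models))
    stop("one pose per component required")
  structure(list(models = models, poses = poses, energy = energy),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat("assembly: ", length(x$models), " components, ",
      sum(vapply(x$models, n_beads, 1L)), " beads\n", sep = "")
  if (!is.null(x$energy)) {
    e <- unlist(x$energy)
    cat("  energies:", paste(names(e), signif(e, 5), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Placed coordinates of a whole assembly
#'
#' @param asm \code{assembly}.
#' @return list with \code{xyz} (all beads stacked), \code{comp} (component
#'   index per bead), \code{weight}, \code{kind}.
#' @export
assembly_coords <- function(asm) {
  xyz <- lapply(seq_along(asm$models),
                function(i) apply_pose(asm$models[[i]], asm$poses[[i]]))
  n <- vapply(xyz, nrow, 1L)
  list(xyz = do.call(rbind, xyz),
       comp = rep(seq_along(asm$models), n),
       weight = unlist(lapply(asm$models, `[[`, "weight")),
       kind = unlist(lapply(asm$models, `[[`, "kind")))
}

# ---- PDB I/O and coarse-graining ------------------------------------------

#' Read a PDB file
#'
#' Thin wrapper over \code{bio3d::read.pdb} keeping ATOM/HETATM records and
#' optionally filtering by chain. Residue numbering is preserved as in the
#' file (1-based PDB convention).
#'
#' @param path PDB file path.
#' @param chain_filter optional character vector of chain IDs to keep.
#' @return a \code{bio3d} \code{pdb} object.
#' @export
read_pdb <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e)))
  if (!is.null(chain_filter)) {
    sel <- bio3d::atom.select(pdb, chain = chain_filter, verbose = FALSE)
    if (length(sel$atom) == 0)
      stop("no atoms left after chain filter '",
           paste(chain_filter, collapse = ","), "'")
    pdb <- bio3d::trim.pdb(pdb, sel)
  }
  if (nrow(pdb$atom) == 0) stop("no atoms in PDB file ", path)
  pdb
}

#' Coarse-grain an atomic structure into beads
#'
#' Default scheme puts one backbone bead on each Calpha and one sidechain
#' bead at the centroid of the sidechain heavy atoms (glycine gets the
#' backbone bead only). Bead weight is the summed atomic mass of the atoms
#' the bead represents. The \code{"all-atom"} scheme passes every heavy atom
#' through as a bead (backbone N, CA, C, O labelled \code{"CA"}).
#'
#' @param pdb a \code{bio3d} \code{pdb} object (see \code{\link{read_pdb}}).
#' @param scheme \code{"calpha+sidechain"} (default) or \code{"all-atom"}.
#' @param name model name.
#' @return \code{coarse_model}; attribute \code{"skipped"} counts residues
#'   dropped for lacking a Calpha atom.
#' @export
coarse_grain <- function(pdb, scheme = c("calpha+sidechain", "all-atom"),
                         name = "model") {
  scheme <- match.arg(scheme)
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM") & !is.na(at$elety), ]
  ele <- suppressWarnings(bio3d::atom2ele(at$elety, rescue = TRUE))
  at <- at[ele != "H", ]
  ele <- ele[ele != "H"]
  etab <- new.env()
  utils::data("elements", package = "bio3d", envir = etab)
  mass <- etab$elements$mass[match(ele, as.character(etab$elements$symb))]
  if (anyNA(mass)) stop("unknown element(s): ",
                        paste(unique(ele[is.na(mass)]), collapse = ", "))
  key <- paste(at$chain, at$resno, at$insert)
  skipped <- 0L
  if (scheme == "all-atom") {
    bb <- at$elety %in% c("N", "CA", "C", "O")
    model <- coarse_model(cbind(at$x, at$y, at$z), weight = mass,
                          kind = ifelse(bb, "CA", "SC"),
                          residue = match(key, unique(key)), name = name)
    # all-atom: ensure residues have a 'CA'-kind bead; coarse_model enforces
    attr(model, "skipped") <- 0L
    return(model)
  }
  xyz <- NULL; w <- NULL; kind <- NULL; resi <- NULL
  ukeys <- unique(key)
  ridx <- 0L
  for (k in ukeys) {
    rows <- which(key == k)
    ca <- rows[at$elety[rows] == "CA"]
    if (length(ca) == 0) { skipped <- skipped + 1L; next }
    ca <- ca[1]
    ridx <- ridx + 1L
    bbrows <- rows[at$elety[rows] %in% c("N", "CA", "C", "O", "OXT")]
    xyz <- rbind(xyz, c(at$x[ca], at$y[ca], at$z[ca]))
    w <- c(w, sum(mass[bbrows]))
    kind <- c(kind, "CA"); resi <- c(resi, ridx)
    scrows <- setdiff(rows, bbrows)
    if (length(scrows) > 0) {
      cen <- c(mean(at$x[scrows]), mean(at$y[scrows]), mean(at$z[scrows]))
      xyz <- rbind(xyz, cen)
      w <- c(w, sum(mass[scrows]))
      kind <- c(kind, "SC"); resi <- c(resi, ridx)
    }
  }
  if (is.null(xyz)) stop("no residues with Calpha atoms found")
  if (skipped > 0)
    warning(skipped, " residue(s) without Calpha skipped")
  model <- coarse_model(xyz, weight = w, kind = kind, residue = resi,
                        name = name)
  attr(model, "skipped") <- skipped
  model
}

#' Write / read a coarse model as a whitespace-delimited table
#'
#' Columns: x y z weight kind residue.
#' @param model \code{coarse_model}.
#' @param path file path.
#' @export
write_coarse_model <- function(model, path) {
  df <- data.frame(x = model$xyz[, 1], y = model$xyz[, 2], z = model$xyz[, 3],
                   weight = model$weight, kind = model$kind,
                   residue = model$residue)
  write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coarse_model
#' @param name model name for the read model.
#' @export
read_coarse_model <- function(path, name = basename(path)) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  coarse_model(cbind(df$x, df$y, df$z), weight = df$weight, kind = df$kind,
               residue = df$residue, name = name)
}

# ---- superposition and RMSD metrics ---------------------------------------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimizing the RMSD of
#' \code{mobile} onto \code{target}; reflections are excluded by
#' construction (det = +1).
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows, n >= 3.
#' @param weight optional per-point weights.
#' @return list with \code{pose} (\code{rigid_pose}) and \code{rmsd} (the
#'   fitted RMSD in Angstrom).
#' @export
superpose <- function(mobile, target, weight = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3 || ncol(target) != 3)
    stop("mobile and target must be matched n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points")
  if (is.null(weight)) weight <- rep(1, n)
  wsum <- sum(weight)
  cm <- colSums(mobile * weight) / wsum
  ct <- colSums(target * weight) / wsum
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  # degenerate (collinear) sets have a rank-deficient covariance
  H <- crossprod(A * weight, B)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear or coincident) point set")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - as.numeric(R %*% cm)
  fitted <- sweep(A %*% t(R), 2, ct, "+")
  rms <- sqrt(sum(weight * rowSums((fitted - target)^2)) / wsum)
  list(pose = rigid_pose(R, t), rmsd = rms)
}

#' Unfitted RMSD between matched coordinate sets
#'
#' Root-mean-square deviation with no fitting or optimization.
#' @param xyz,ref matched n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(xyz, ref) {
  xyz <- as.matrix(xyz); ref <- as.matrix(ref)
  if (!all(dim(xyz) == dim(ref)))
    stop("coordinate sets must have matching dimensions")
  sqrt(mean(rowSums((xyz - ref)^2)))
}

#' Unfitted RMSD between two assemblies
#'
#' Computes \code{\link{rmsd}} over all beads. For homo-oligomers, rings of
#' identical components admit equivalent relabelings (e.g. cyclic shifts);
#' supply these as \code{equivalences} (a list of permutations of component
#' indices) and the minimum RMSD over all of them is returned.
#'
#' @param asm,ref assemblies with identical component models.
#' @param equivalences optional list of integer permutations of components.
#' @return RMSD in Angstrom.
#' @export
assembly_rmsd <- function(asm, ref, equivalences = NULL) {
  cref <- assembly_coords(ref)
  if (is.null(equivalences)) equivalences <- list(seq_along(asm$models))
  best <- Inf
  for (perm in equivalences) {
    a2 <- assembly(asm$models[perm], asm$poses[perm])
    best <- min(best, rmsd(assembly_coords(a2)$xyz, cref$xyz))
  }
  best
}

#' Ligand RMSD between two assemblies
#'
#' For each (receptor, ligand) component pair the model receptor is fitted
#' onto the reference receptor, the fitted transform is applied to the model
#' ligand, and the unfitted RMSD of the ligand is computed. The average over
#' all pairs is returned, measuring relative (not absolute) placement.
#'
#' @param asm,ref assemblies with matched components.
#' @param pairs 2-column integer matrix (receptor index, ligand index).
#' @return average ligand RMSD in Angstrom.
#' @export
ligand_rmsd <- function(asm, ref, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0) stop("empty pair list")
  nc <- length(asm$models)
  if (any(pairs < 1 | pairs > nc)) stop("pair indices out of range")
  vals <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    rec <- pairs[i, 1]; lig <- pairs[i, 2]
    fit <- superpose(apply_pose(asm$models[[rec]], asm$poses[[rec]]),
                     apply_pose(ref$models[[rec]], ref$poses[[rec]]))
    lig_m <- transform_xyz(apply_pose(asm$models[[lig]], asm$poses[[lig]]),
                           fit$pose)
    vals[i] <- rmsd(lig_m, apply_pose(ref$models[[lig]], ref$poses[[lig]]))
  }
  mean(vals)
}
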