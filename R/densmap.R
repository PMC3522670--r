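# Regular 3D density grids: values live at voxel centers; the world
# coordinate of voxel (i,j,k) (1-based) is origin + voxel_size*(i-1,j-1,k-1).

#' Construct a density grid
#'
#' @param values 3D numeric array (x index fastest).
#' @param origin world coordinate (Angstrom) of the center of voxel (1,1,1).
#' @param voxel_size isotropic voxel edge length (Angstrom).
#' @param resolution nominal resolution label (Angstrom) or NA.
#' @return object of class \code{density_grid}.
#' @export
density_grid <- function(values, origin = c(0, 0, 0), voxel_size = 1,
                         resolution = NA_real_) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3D array")
  if (any(dim(values) < 2)) stop("grid dims must be >= 2 in each axis")
  if (!all(is.finite(values))) stop("grid values must be finite")
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be positive")
  structure(list(values = values, origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size),
                 resolution = as.numeric(resolution)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("density_grid ", d[1], "x", d[2], "x", d[3], ", voxel ",
      signif(x$voxel_size, 4), " A, origin (",
      paste(signif(x$origin, 4), collapse = ", "), ")",
      if (is.finite(x$resolution)) paste0(", resolution ", x$resolution, " A"),
      ", sum ", signif(sum(x$values), 6), "\n", sep = "")
  invisible(x)
}

grid_sum <- function(grid) sum(grid$values)

# world coordinates of all voxel centers along one axis
axis_coords <- function(grid, axis) {
  grid$origin[axis] + grid$voxel_size * (seq_len(dim(grid$values)[axis]) - 1)
}

#' Gaussian width from nominal map resolution
#'
#' The standard deviation used for both atom and voxel Gaussians is half the
#' map resolution divided by sqrt(3) per Cartesian axis, so that the total
#' 3D width of a Gaussian matches half the resolution.
#'
#' @param resolution map resolution in Angstrom (> 0).
#' @param divisor per-axis divisor; sqrt(3) by default, configurable.
#' @return sigma in Angstrom.
#' @export
sigma_from_resolution <- function(resolution, divisor = sqrt(3)) {
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be positive")
  (resolution / 2) / divisor
}

#' Gaussian parameters for beads/voxels at a given resolution
#'
#' @param resolution map resolution (Angstrom).
#' @param amplitude Gaussian amplitude.
#' @return list with \code{sigma} (Angstrom), decay \code{s} = 1/(2 sigma^2)
#'   (Angstrom^-2) and \code{amplitude}.
#' @export
gaussian_params <- function(resolution, amplitude = 1) {
  sigma <- sigma_from_resolution(resolution)
  if (amplitude <= 0) stop("amplitude must be positive")
  list(sigma = sigma, s = 1 / (2 * sigma^2), amplitude = amplitude)
}

#' Simulate a density map from a model or assembly
#'
#' Each bead contributes an isotropic Gaussian of width
#' \code{sigma_from_resolution(resolution)} whose integral equals the bead
#' weight, sampled at voxel centers. The default voxel size keeps the
#' resolution-to-voxel ratio of 4 used throughout.
#'
#' @param x \code{coarse_model} or \code{assembly}.
#' @param resolution nominal resolution (Angstrom).
#' @param voxel_size voxel edge (Angstrom); default \code{resolution/4}.
#' @param padding extra margin around the coordinates (Angstrom).
#' @param geometry optional existing \code{density_grid} whose geometry
#'   (origin, voxel size, dims) is reused instead of auto-bounding.
#' @return \code{density_grid}.
#' @export
simulate_map <- function(x, resolution, voxel_size = resolution / 4,
                         padding = 1.5 * resolution, geometry = NULL) {
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be positive")
  if (inherits(x, "coarse_model")) {
    xyz <- x$xyz; w <- x$weight
  } else if (inherits(x, "assembly")) {
    cc <- assembly_coords(x); xyz <- cc$xyz; w <- cc$weight
  } else stop("x must be a coarse_model or assembly")
  if (nrow(xyz) < 1) stop("empty model")
  if (resolution / voxel_size < 3.999)
    if (abs(resolution / voxel_size - 4) > 1e-6)
      warning("resolution-to-voxel ratio is ", signif(resolution / voxel_size, 3),
              "; the assembly and GVM machinery is tuned for a ratio of 4")
  sigma <- sigma_from_resolution(resolution)
  if (is.null(geometry)) {
    lo <- apply(xyz, 2, min) - padding
    hi <- apply(xyz, 2, max) + padding
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
    origin <- lo
  } else {
    dims <- dim(geometry$values); origin <- geometry$origin
    voxel_size <- geometry$voxel_size
  }
  amp <- w / (2 * pi * sigma^2)^1.5
  gx <- gauss_profile(origin[1], voxel_size, dims[1], xyz[, 1], sigma)
  gy <- gauss_profile(origin[2], voxel_size, dims[2], xyz[, 2], sigma)
  gz <- gauss_profile(origin[3], voxel_size, dims[3], xyz[, 3], sigma)
  vals <- array(0, dims)
  for (k in seq_len(dims[3])) {
    # slice k: sum_b amp_b gx[,b] gy[,b]^T gz[k,b]
    vals[, , k] <- gx %*% (t(gy) * (amp * gz[k, ]))
  }
  density_grid(vals, origin, voxel_size, resolution)
}

# n x nb matrix of exp(-(X_i - c_b)^2 / (2 sigma^2))
gauss_profile <- function(orig, vox, n, centers, sigma) {
  X <- orig + vox * (seq_len(n) - 1)
  exp(-outer(X, centers, "-")^2 / (2 * sigma^2))
}

#' Downsample a grid by joining voxels
#'
#' Each output voxel is the sum of the \code{factor^3} input voxels it
#' covers (joining, not averaging), so the density sum is conserved exactly.
#' Dimensions not divisible by \code{factor} are zero-padded first.
#'
#' @param grid \code{density_grid}.
#' @param factor integer >= 2.
#' @return \code{density_grid} with voxel size multiplied by \code{factor}.
#' @export
downsample_join <- function(grid, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 2) stop("factor must be >= 2")
  v <- grid$values
  d <- dim(v)
  dpad <- as.integer(ceiling(d / factor) * factor)
  if (any(dpad != d)) {
    vp <- array(0, dpad)
    vp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- v
    v <- vp; d <- dpad
  }
  nd <- d %/% factor
  out <- array(0, nd)
  for (dx in seq_len(factor)) for (dy in seq_len(factor))
    for (dz in seq_len(factor)) {
      out <- out + v[seq(dx, d[1], by = factor),
                     seq(dy, d[2], by = factor),
                     seq(dz, d[3], by = factor)]
    }
  # new voxel centers sit at the centroid of the joined block
  new_origin <- grid$origin + grid$voxel_size * (factor - 1) / 2
  density_grid(out, new_origin, grid$voxel_size * factor, grid$resolution)
}

# Separable convolution of a 3D array with a 1D kernel per axis (zero
# padding outside the grid). kern is a function(offset_in_A) -> value.
separable_convolve <- function(vals, voxel, kfun_x, kfun_y = kfun_x,
                               kfun_z = kfun_x) {
  d <- dim(vals)
  conv_axis <- function(v, n, kfun, axis) {
    off <- voxel * outer(seq_len(n), seq_len(n), "-")
    K <- kfun(off)
    if (axis == 1) {
      dim(v) <- c(d[1], d[2] * d[3])
      out <- K %*% v
      dim(out) <- d
    } else if (axis == 2) {
      out <- array(0, d)
      for (k in seq_len(d[3])) out[, , k] <- v[, , k] %*% t(K)
    } else {
      dim(v) <- c(d[1] * d[2], d[3])
      out <- v %*% t(K)
      dim(out) <- d
    }
    out
  }
  v <- conv_axis(vals, d[1], kfun_x, 1)
  v <- conv_axis(v, d[2], kfun_y, 2)
  conv_axis(v, d[3], kfun_z, 3)
}

#' Low-pass filter a map to a coarser resolution
#'
#' Gaussian convolution with the kernel width that makes the combined width
#' equal \code{sigma_from_resolution(target_resolution)}. The density sum is
#' conserved up to losses at the grid edges (reported as an attribute).
#'
#' @param grid \code{density_grid} with a finite \code{resolution} label.
#' @param target_resolution target resolution, coarser than the current one.
#' @return filtered \code{density_grid}; attribute \code{"edge_loss"} gives
#'   the relative density sum lost at the edges.
#' @export
lowpass_filter <- function(grid, target_resolution) {
  if (!is.finite(grid$resolution))
    stop("grid has no resolution label")
  if (target_resolution <= grid$resolution)
    stop("target resolution must be coarser than the current ",
         grid$resolution, " A")
  s0 <- sigma_from_resolution(grid$resolution)
  s1 <- sigma_from_resolution(target_resolution)
  sk <- sqrt(s1^2 - s0^2)
  h <- grid$voxel_size
  kfun <- function(off) exp(-off^2 / (2 * sk^2)) * h / sqrt(2 * pi * sk^2)
  out <- separable_convolve(grid$values, h, kfun)
  loss <- 1 - sum(out) / sum(grid$values)
  g <- density_grid(out, grid$origin, h, target_resolution)
  attr(g, "edge_loss") <- loss
  g
}

#' Deconvolve a Gaussian point-spread function from a map
#'
#' Approximate inverse of an isotropic Gaussian blur. \code{"wiener"}
#' (default) applies the regularized inverse filter in Fourier space on a
#' zero-padded copy; \code{"richardson-lucy"} iterates the multiplicative
#' update on nonnegative maps.
#'
#' @param grid \code{density_grid}.
#' @param psf_sigma Gaussian PSF sigma (Angstrom, > 0).
#' @param method \code{"wiener"} or \code{"richardson-lucy"}.
#' @param regularizer Wiener regularization constant.
#' @param iterations Richardson-Lucy iteration count.
#' @return \code{density_grid}; attribute \code{"converged"} is FALSE with a
#'   warning if Richardson-Lucy did not settle.
#' @export
deconvolve <- function(grid, psf_sigma, method = c("wiener", "richardson-lucy"),
                       regularizer = 1e-8, iterations = 50) {
  method <- match.arg(method)
  if (!is.finite(psf_sigma) || psf_sigma < 0) stop("psf sigma must be >= 0")
  h <- grid$voxel_size
  if (psf_sigma == 0) {
    out <- grid
    attr(out, "converged") <- TRUE
    return(out)
  }
  d <- dim(grid$values)
  pad <- as.integer(min(ceiling(4 * psf_sigma / h), 24))
  dp <- d + 2L * pad
  y <- array(0, dp)
  y[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    grid$values
  # centered, wrapped PSF (sum-normalized so total density is preserved)
  psf1 <- function(n) {
    idx <- seq_len(n) - 1
    off <- pmin(idx, n - idx) * h
    k <- exp(-off^2 / (2 * psf_sigma^2))
    k / sum(k)
  }
  px <- psf1(dp[1]); py <- psf1(dp[2]); pz <- psf1(dp[3])
  P <- outer(outer(px, py), pz)
  H <- fft(P)
  if (method == "wiener") {
    X <- fft(y) * Conj(H) / (Mod(H)^2 + regularizer)
    out <- Re(fft(X, inverse = TRUE)) / prod(dp)
    converged <- TRUE
  } else {
    conv <- function(a, Hf) Re(fft(fft(a) * Hf, inverse = TRUE)) / prod(dp)
    if (min(y) < 0) stop("richardson-lucy requires a nonnegative map")
    x <- y + 1e-12
    converged <- FALSE
    for (it in seq_len(iterations)) {
      est <- conv(x, H)
      ratio <- y / pmax(est, 1e-12)
      xnew <- x * conv(ratio, Conj(H))
      if (max(abs(xnew - x)) < 1e-8 * max(abs(y))) {
        x <- xnew; converged <- TRUE; break
      }
      x <- xnew
    }
    out <- x
    if (!converged)
      warning("richardson-lucy did not converge in ", iterations,
              " iterations; returning best iterate")
  }
  res <- density_grid(out[pad + seq_len(d[1]), pad + seq_len(d[2]),
                          pad + seq_len(d[3])],
                      grid$origin, h, grid$resolution)
  attr(res, "converged") <- converged
  res
}

#' Rescale a grid to a target density sum
#'
#' @param grid \code{density_grid} with nonzero sum.
#' @param target_sum desired sum of voxel values.
#' @return rescaled \code{density_grid}.
#' @export
rescale_to_sum <- function(grid, target_sum) {
  s <- sum(grid$values)
  if (s == 0) stop("cannot rescale a zero-sum grid")
  density_grid(grid$values * (target_sum / s), grid$origin,
               grid$voxel_size, grid$resolution)
}
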