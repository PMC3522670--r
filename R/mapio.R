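# Map I/O: MRC/CCP4 2014 (mode 2, float32) and Situs ASCII. Only isotropic
# voxels and axis order x,y,z (mapc,mapr,maps = 1,2,3) are supported.

#' Read a density map from file
#'
#' @param path file path.
#' @param format \code{"mrc"} or \code{"situs"}; guessed from the extension
#'   (.mrc/.map vs .sit/.situs) when missing.
#' @return \code{density_grid}. The stored origin is the world coordinate of
#'   the first voxel center.
#' @export
read_map <- function(path, format = c("auto", "mrc", "situs")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_map_format(path)
  if (!file.exists(path)) stop("map file not found: ", path)
  switch(format, mrc = read_mrc(path), situs = read_situs(path))
}

#' Write a density map to file
#'
#' @param grid \code{density_grid}.
#' @param path file path.
#' @param format \code{"mrc"} or \code{"situs"} (guessed from extension).
#' @export
write_map <- function(grid, path, format = c("auto", "mrc", "situs")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_map_format(path)
  switch(format, mrc = write_mrc(grid, path), situs = write_situs(grid, path))
  invisible(path)
}

guess_map_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("mrc", "map", "ccp4")) return("mrc")
  if (ext %in% c("sit", "situs")) return("situs")
  stop("cannot guess map format from extension '", ext,
       "'; pass format explicitly")
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mxyz <- hdr_int[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  invisible(readBin(con, "raw", n = 4 * 25))      # extra words 26-49 (incl.)
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  maptag <- rawToChar(readBin(con, "raw", n = 4))
  invisible(readBin(con, "raw", n = 812))  # machst, rms, nlabl, labels
  if (mode != 2)
    stop("unsupported MRC mode ", mode, " (only mode 2 float32)")
  if (!all(mapcrs == c(1, 2, 3)))
    stop("unsupported MRC axis order (mapc,mapr,maps must be 1,2,3)")
  vox <- cella / mxyz
  if (max(vox) - min(vox) > 1e-4 * max(vox))
    stop("anisotropic voxels not supported (", paste(signif(vox, 5),
         collapse = ", "), ")")
  if (ispg[2] > 0) stop("MRC symmetry records not supported")
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                  endian = "little")
  if (length(vals) != nx * ny * nz)
    stop("MRC data truncated: expected ", nx * ny * nz, " voxels, got ",
         length(vals))
  density_grid(array(vals, c(nx, ny, nz)), origin = origin,
               voxel_size = mean(vox))
}

write_mrc <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  w_f <- function(x) writeBin(as.numeric(x), con, size = 4,
                              endian = "little")
  w_i(d)                                   # nx ny nz
  w_i(2)                                   # mode 2
  w_i(c(0, 0, 0))                          # nxstart
  w_i(d)                                   # mx my mz
  w_f(d * grid$voxel_size)                 # cella
  w_f(c(90, 90, 90))                       # cellb
  w_i(c(1, 2, 3))                          # mapc mapr maps
  v <- grid$values
  w_f(c(min(v), max(v), mean(v)))          # dmin dmax dmean
  w_i(c(1, 0))                             # ispg, nsymbt
  w_i(rep(0, 25))                          # extra
  w_f(grid$origin)                         # origin (words 50-52)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machst little-endian
  w_f(sd(as.numeric(v)))                   # rms
  w_i(0)                                   # nlabl
  writeBin(raw(800), con)                  # labels
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

read_situs <- function(path) {
  first <- scan(path, what = numeric(), nlines = 1, quiet = TRUE)
  if (length(first) != 7)
    stop("malformed Situs header: expected 7 numbers, got ", length(first))
  vox <- first[1]; origin <- first[2:4]; dims <- as.integer(first[5:7])
  vals <- scan(path, what = numeric(), skip = 1, quiet = TRUE)
  if (length(vals) != prod(dims))
    stop("Situs data size mismatch: header says ", prod(dims),
         " voxels, file has ", length(vals))
  density_grid(array(vals, dims), origin = origin, voxel_size = vox)
}

write_situs <- function(grid, path) {
  d <- dim(grid$values)
  hdr <- paste(c(format(grid$voxel_size, digits = 10),
                 format(grid$origin, digits = 10), d), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("", con)
  vals <- format(as.numeric(grid$values), digits = 8)
  n <- length(vals)
  idx <- split(seq_len(n), (seq_len(n) - 1) %/% 10)
  writeLines(vapply(idx, function(i) paste(vals[i], collapse = " "), ""), con)
  invisible(path)
}
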