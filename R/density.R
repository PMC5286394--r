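# Density maps on a regular cubic grid. Convention (used everywhere):
# voxel indices are 0-based and voxel-centered; the physical position of
# voxel (i,j,k) is origin + (i,j,k) * voxel (Angstrom). The values array
# is ordered x-fastest, i.e. values[i+1, j+1, k+1].

#' Construct a density map
#'
#' @param values 3D numeric array (x index fastest).
#' @param voxel isotropic voxel size in Angstrom.
#' @param origin numeric(3): physical position (Angstrom) of voxel
#'   (0,0,0).
#' @param resolution optional declared resolution in Angstrom.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, voxel, origin = c(0, 0, 0),
                        resolution = NULL) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (!all(is.finite(values))) stop("map contains non-finite values")
  if (!is.numeric(voxel) || length(voxel) != 1L || voxel <= 0)
    stop("voxel size must be a positive scalar")
  structure(list(values = values, voxel = as.numeric(voxel),
                 origin = as.numeric(origin),
                 resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, %.3f A/voxel, origin (%.1f, %.1f, %.1f)\n",
              d[1], d[2], d[3], x$voxel, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# internal: are two maps on the same grid?
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$voxel - b$voxel) < tol && all(abs(a$origin - b$origin) < tol)
}

#' Read an MRC/CCP4 density map
#'
#' Reads the 2014 dialect of the MRC format. Axis order is normalized to
#' x-fastest; modes 0 (int8), 1 (int16), 2 (float32), and 6 (uint16) are
#' promoted to double. Non-cubic voxels are rejected. The physical origin
#' is the MRC origin record plus any start-index offset.
#'
#' @param path file path.
#' @return A `density_map`.
#' @export
read_density <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_f <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_i[1:3]            # column, row, section counts
  mode <- hdr_i[4]
  nstart <- hdr_i[5:7]
  mxyz <- hdr_i[8:10]
  cella <- hdr_f[11:13]
  mapcrs <- hdr_i[17:19]        # axis of columns/rows/sections (1=x,2=y,3=z)
  nsymbt <- hdr_i[24]
  orig <- hdr_f[50:52]          # MRC2014 origin words
  if (any(nxyz <= 0)) stop("unsupported dialect: bad dimensions in ", path)
  if (!all(sort(mapcrs) == 1:3))
    stop("unsupported dialect: bad axis order in ", path)
  vox <- cella / mxyz
  if (any(!is.finite(vox)) || any(vox <= 0))
    stop("unsupported dialect: bad cell in ", path)
  if (max(vox) - min(vox) > 1e-4 * max(vox))
    stop("unsupported dialect: non-cubic voxels in ", path)
  seek(con, 1024 + max(0, nsymbt))
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             signed = FALSE, endian = "little")),
    stop("unsupported MRC mode ", mode, " in ", path))
  if (length(vals) != n) stop("truncated map data in ", path)
  arr <- array(vals, dim = nxyz)
  # permute so that dimension 1 is x, 2 is y, 3 is z
  perm <- order(mapcrs)                 # position of x, y, z among axes
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)
  # reorder per-axis metadata into x,y,z order
  nstart_xyz <- nstart[perm]
  origin <- orig + nstart_xyz * vox[1]
  density_map(arr, voxel = vox[1], origin = origin)
}

#' Write an MRC/CCP4 density map
#'
#' Writes mode-2 (float32) MRC2014 with x-fastest axis order and the
#' physical origin in the origin record. Values, voxel size, and origin
#' round-trip bit-exactly at float32 precision.
#'
#' @param map a `density_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density <- function(map, path) {
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  vals <- as.numeric(map$values)
  wi(d); wi(2); wi(c(0, 0, 0)); wi(d)          # nxyz, mode, nstart, mxyz
  wf(d * map$voxel); wf(c(90, 90, 90))         # cella, cellb
  wi(c(1, 2, 3))                               # mapc, mapr, maps
  wf(c(min(vals), max(vals), mean(vals)))      # dmin, dmax, dmean
  wi(1); wi(0)                                 # ispg, nsymbt
  wi(rep(0, 25))                               # extra (words 26-49)
  wf(map$origin)                               # origin x,y,z (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(vals) * sqrt((length(vals) - 1) / length(vals)))  # rms
  wi(0)                                        # nlabl
  writeBin(raw(800), con)                      # labels
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}

#' Physical coordinates of all voxel centers
#'
#' @param map a `density_map`.
#' @return list of axis coordinate vectors `x`, `y`, `z` (Angstrom).
#' @export
voxel_axes <- function(map) {
  d <- dim(map$values)
  list(x = map$origin[1] + (seq_len(d[1]) - 1) * map$voxel,
       y = map$origin[2] + (seq_len(d[2]) - 1) * map$voxel,
       z = map$origin[3] + (seq_len(d[3]) - 1) * map$voxel)
}

#' Resample a map onto another map's grid
#'
#' Trilinear interpolation; points outside the source grid are filled
#' with `fill`.
#'
#' @param map source `density_map`.
#' @param target `density_map` whose grid to adopt.
#' @param fill value for out-of-grid points.
#' @return A `density_map` on `target`'s grid.
#' @export
resample_map <- function(map, target, fill = 0) {
  if (same_grid(map, target)) return(map)
  ax <- voxel_axes(target)
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z,
                               KEEP.OUT.ATTRS = FALSE))
  v <- cpp_trilinear(as.numeric(map$values), dim(map$values), map$origin,
                     map$voxel, pts, fill)
  density_map(array(v, dim(target$values)), target$voxel, target$origin,
              resolution = map$resolution)
}
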