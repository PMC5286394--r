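# Map algebra and comparison: density simulation, normalized
# cross-correlation, Fourier filtering, mirroring, cyclic
# symmetrization, difference maps, FSC, and volume coverage.

# Gaussian width convention: sigma = resolution / (pi * sqrt(2)), so the
# Fourier amplitude of the kernel falls to 1/e at spatial frequency
# 1/resolution.
resolution_sigma <- function(resolution) resolution / (pi * sqrt(2))

#' Simulate a density map from a model
#'
#' Each atom (or bead) contributes an isotropic Gaussian with weight
#' proportional to its mass: one residue mass per Calpha atom, `span`
#' residue masses per bead. Kernels are truncated at 4 sigma; the map
#' integral times voxel volume equals the total weight to within the
#' truncation error (< 0.2%).
#'
#' @param model an `atomic_model` or `bead_model`.
#' @param resolution target resolution in Angstrom (>= 2 voxels).
#' @param voxel voxel size in Angstrom.
#' @param padding margin around the model bounding box, Angstrom;
#'   defaults to the resolution.
#' @param grid optional `density_map` whose grid to reuse instead of
#'   deriving one from the model extent.
#' @return A `density_map` with `resolution` set.
#' @export
simulate_density <- function(model, resolution, voxel = resolution / 4,
                             padding = resolution, grid = NULL) {
  if (resolution < 2 * voxel)
    stop("resolution must be at least twice the voxel size")
  if (inherits(model, "bead_model")) {
    coords <- as.matrix(model[, c("x", "y", "z")])
    w <- as.numeric(model$span)
  } else {
    at <- if (inherits(model, "atomic_model")) model$atoms else model
    if (nrow(at) == 0L) stop("empty model")
    coords <- as.matrix(at[, c("x", "y", "z")])
    w <- rep(1, nrow(coords))
  }
  if (nrow(coords) == 0L) stop("empty model")
  sigma <- resolution_sigma(resolution)
  if (is.null(grid)) {
    lo <- apply(coords, 2, min) - padding
    hi <- apply(coords, 2, max) + padding
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
    origin <- lo
  } else {
    dims <- dim(grid$values)
    origin <- grid$origin
    voxel <- grid$voxel
  }
  v <- cpp_simulate_density(coords, w, sigma, origin, dims, voxel)
  density_map(array(v, dims), voxel, origin, resolution = resolution)
}

#' Normalized cross-correlation of two maps
#'
#' Pearson correlation of voxel values over a mask. `mask = "overlap"`
#' restricts to voxels where both maps are nonzero; `"threshold"` to
#' voxels where both exceed `contour`; `"all"` uses every voxel. Maps on
#' different grids are first resampled onto the first map's grid.
#'
#' @param mapA,mapB `density_map` objects.
#' @param mask `"overlap"`, `"threshold"`, or `"all"`.
#' @param contour numeric contour for `mask = "threshold"`.
#' @return Correlation in `[-1, 1]`.
#' @export
ncc <- function(mapA, mapB, mask = c("overlap", "threshold", "all"),
                contour = 0) {
  mask <- match.arg(mask)
  if (!same_grid(mapA, mapB)) mapB <- resample_map(mapB, mapA)
  a <- as.numeric(mapA$values); b <- as.numeric(mapB$values)
  keep <- switch(mask,
                 overlap = abs(a) > 0 & abs(b) > 0,
                 threshold = a >= contour & b >= contour,
                 all = rep(TRUE, length(a)))
  if (sum(keep) < 2) stop("undefined correlation: empty mask")
  a <- a[keep]; b <- b[keep]
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined correlation: constant map over mask")
  cor(a, b)
}

# internal: |frequency| grid (1/Angstrom) for an FFT of this map
freq_grid <- function(map) {
  d <- dim(map$values)
  fax <- function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    k / (n * map$voxel)
  }
  fx <- fax(d[1]); fy <- fax(d[2]); fz <- fax(d[3])
  sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
}

#' Low-pass filter a map
#'
#' Fourier-space Gaussian attenuation `exp(-(f * resolution)^2)`: the
#' amplitude falls to 1/e at spatial frequency `1/resolution` and the
#' mean (f = 0) is preserved. Two successive filters at R1 and R2 equal
#' one filter at `sqrt(R1^2 + R2^2)`.
#'
#' @param map a `density_map`.
#' @param resolution cutoff in Angstrom (>= 2 voxels).
#' @return The filtered `density_map`.
#' @export
lowpass_filter <- function(map, resolution) {
  if (resolution < 2 * map$voxel)
    stop("resolution must be at least twice the voxel size")
  f <- freq_grid(map)
  H <- exp(-(f * resolution)^2)
  v <- Re(fft(fft(map$values) * H, inverse = TRUE)) / length(map$values)
  density_map(array(v, dim(map$values)), map$voxel, map$origin,
              resolution = resolution)
}

#' Mirror a map
#'
#' Reflects the values through the plane `x = center` (a pure index
#' flip), producing the opposite hand. Applying twice returns the
#' original bit-exactly.
#'
#' @param map a `density_map`.
#' @return The mirrored `density_map`.
#' @export
mirror_map <- function(map) {
  d <- dim(map$values)
  density_map(map$values[d[1]:1, , , drop = FALSE], map$voxel, map$origin,
              resolution = map$resolution)
}

#' Cyclic symmetrization of a map
#'
#' Averages the map over the cyclic group C\eqn{n} about an axis through
#' the map center. For C2 about a grid axis the operation is an exact
#' index rotation (no interpolation, mean preserved exactly); other
#' orders use trilinear resampling.
#'
#' @param map a `density_map`.
#' @param order symmetry order (>= 2).
#' @param axis rotation axis, default z.
#' @return The symmetrized `density_map`.
#' @export
apply_symmetry <- function(map, order = 2, axis = c(0, 0, 1)) {
  if (order < 2) stop("symmetry order must be >= 2")
  d <- dim(map$values)
  center <- map$origin + (d - 1) / 2 * map$voxel
  on_axis <- which(abs(axis) / sqrt(sum(axis^2)) > 1 - 1e-12)
  if (order == 2 && length(on_axis) == 1) {
    # exact 180-degree index rotation about the grid axis through center
    idx <- list(d[1]:1, d[2]:1, d[3]:1)
    idx[[on_axis]] <- seq_len(d[on_axis])
    rot <- map$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out <- (map$values + rot) / 2
    return(density_map(array(out, d), map$voxel, map$origin,
                       resolution = map$resolution))
  }
  ax <- voxel_axes(map)
  pts <- as.matrix(expand.grid(x = ax$x, y = ax$y, z = ax$z,
                               KEEP.OUT.ATTRS = FALSE))
  acc <- as.numeric(map$values)
  for (m in seq_len(order - 1)) {
    R <- axis_angle_matrix(axis, -2 * pi * m / order)
    src <- sweep(sweep(pts, 2, center) %*% t(R), 2, center, "+")
    acc <- acc + cpp_trilinear(as.numeric(map$values), d, map$origin,
                               map$voxel, src, 0)
  }
  density_map(array(acc / order, d), map$voxel, map$origin,
              resolution = map$resolution)
}

#' Difference map between two reconstructions
#'
#' Both maps are low-pass filtered to a common resolution, intensity
#' normalized (zero mean, unit variance over the grid -- negative-stain
#' intensity scales are arbitrary), and subtracted voxelwise (A - B).
#'
#' @param mapA,mapB `density_map` objects (B is resampled onto A's grid
#'   if needed).
#' @param common_resolution filter target in Angstrom, default 35.
#' @return A `density_map` of normalized differences.
#' @export
difference_map <- function(mapA, mapB, common_resolution = 35) {
  if (!same_grid(mapA, mapB)) mapB <- resample_map(mapB, mapA)
  a <- lowpass_filter(mapA, common_resolution)$values
  b <- lowpass_filter(mapB, common_resolution)$values
  za <- if (sd(a) > 0) (a - mean(a)) / sd(a) else a - mean(a)
  zb <- if (sd(b) > 0) (b - mean(b)) / sd(b) else b - mean(b)
  density_map(za - zb, mapA$voxel, mapA$origin,
              resolution = common_resolution)
}

#' Fourier shell correlation
#'
#' Per-shell normalized complex correlation of the two maps' Fourier
#' transforms; shell width is one Fourier voxel.
#'
#' @param mapA,mapB `density_map` objects on the same grid.
#' @return data.frame of class `fsc_curve`: `freq` (1/Angstrom, shell
#'   centers), `fsc`, `n_voxels`.
#' @export
fsc <- function(mapA, mapB) {
  if (!same_grid(mapA, mapB)) stop("maps must share a grid")
  d <- dim(mapA$values)
  FA <- fft(mapA$values); FB <- fft(mapB$values)
  f <- freq_grid(mapA)
  n <- min(d)
  shell <- round(f * n * mapA$voxel)       # radius in Fourier voxels
  smax <- floor(n / 2)
  keep <- shell <= smax
  shell <- shell[keep]
  num <- Re(FA * Conj(FB))[keep]
  pa <- (Mod(FA)^2)[keep]; pb <- (Mod(FB)^2)[keep]
  sn <- tapply(num, shell, sum)
  sa <- tapply(pa, shell, sum)
  sb <- tapply(pb, shell, sum)
  cnt <- tapply(rep(1, length(shell)), shell, sum)
  denom <- sqrt(sa * sb)
  val <- ifelse(denom > 0, sn / denom, NA_real_)
  out <- data.frame(freq = as.numeric(names(sn)) / (n * mapA$voxel),
                    fsc = as.numeric(val), n_voxels = as.integer(cnt))
  out <- out[order(out$freq), ]
  rownames(out) <- NULL
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' Returns `1/frequency` at the first downward crossing of the threshold
#' (linear interpolation between shells). If the curve never crosses,
#' returns the Nyquist resolution with attribute `crossed = FALSE`.
#'
#' @param curve an `fsc_curve`.
#' @param threshold FSC threshold, conventionally 0.143 or 0.5.
#' @param voxel voxel size (Angstrom) for the Nyquist fallback; inferred
#'   from the curve's maximum frequency when `NULL`.
#' @return Resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.143, voxel = NULL) {
  cv <- curve[curve$freq > 0 & is.finite(curve$fsc), ]
  below <- which(cv$fsc < threshold)
  if (!length(below)) {
    nyq <- if (!is.null(voxel)) 2 * voxel else 1 / max(cv$freq)
    return(structure(nyq, crossed = FALSE))
  }
  i <- below[1]
  if (i == 1) return(structure(1 / cv$freq[1], crossed = TRUE))
  f1 <- cv$freq[i - 1]; f2 <- cv$freq[i]
  v1 <- cv$fsc[i - 1]; v2 <- cv$fsc[i]
  fc <- f1 + (v1 - threshold) / (v1 - v2) * (f2 - f1)
  structure(1 / fc, crossed = TRUE)
}

#' Fraction of map volume covered by a model
#'
#' Fraction of voxels above the contour whose centers lie inside the
#' model's bead-radius envelope. When no contour is given it is chosen
#' so that the enclosed volume equals the expected molecular volume
#' (1.21 A^3/Da x assembly mass at 110 Da/residue).
#'
#' @param map a `density_map`.
#' @param beads a `bead_model` placed in the map frame (may have zero
#'   rows, giving coverage 0).
#' @param contour density contour; `NULL` for the volume-matched choice.
#' @param radius_scale multiplier on bead radii (envelope generosity).
#' @return Fraction in `[0, 1]`.
#' @export
volume_coverage <- function(map, beads, contour = NULL, radius_scale = 1) {
  v <- as.numeric(map$values)
  if (is.null(contour)) {
    n_res <- sum(beads$span)
    mol_vol <- 1.21 * 110 * n_res              # A^3
    n_target <- max(1, round(mol_vol / map$voxel^3))
    n_target <- min(n_target, length(v))
    contour <- sort(v, decreasing = TRUE)[n_target]
  }
  if (contour > max(v)) stop("contour above map maximum")
  sel <- which(v >= contour)
  if (!length(sel)) return(0)
  if (is.null(beads) || nrow(beads) == 0L) return(0)
  d <- dim(map$values)
  covered <- logical(length(v))
  for (i in seq_len(nrow(beads))) {
    r <- beads$radius[i] * radius_scale
    ci <- (c(beads$x[i], beads$y[i], beads$z[i]) - map$origin) / map$voxel
    lo <- pmax(0L, as.integer(floor(ci - r / map$voxel)))
    hi <- pmin(d - 1L, as.integer(ceiling(ci + r / map$voxel)))
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dz2 <- ((iz - ci[3]) * map$voxel)^2
    dy2 <- ((iy - ci[2]) * map$voxel)^2
    dx2 <- ((ix - ci[1]) * map$voxel)^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    idx <- as.vector(outer(outer(ix + 1L, iy * d[1], "+"),
                           iz * d[1] * d[2], "+"))
    covered[idx[as.vector(inside)]] <- TRUE
  }
  mean(covered[sel])
}
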