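# Shared in-code fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a straight-chain toy model: n residues along +x, 3.8 A apart
line_model <- function(n = 10, chain = "A", origin = c(0, 0, 0)) {
  atomic_model(data.frame(
    chain = chain, resno = seq_len(n), resname = "ALA", elety = "CA",
    x = origin[1] + (seq_len(n) - 1) * 3.8, y = origin[2], z = origin[3],
    stringsAsFactors = FALSE))
}

# a compact random-walk single body with its simulated map
small_body_case <- function() cached("small_body", function() {
  truth <- generate_assembly(1, body_size = 100, seed = 3)
  map <- simulate_noisy_map(truth, resolution = 25, noise_sd = 0,
                            voxel = 4, seed = 1)
  list(truth = truth,
       body = body_model(truth$model, truth$bodies[[1]]),
       map = map)
})

# a two-body ground truth with a clean 25 A map
two_body_case <- function(seed = 5) {
  truth <- generate_assembly(2, body_size = c(130, 95), seed = seed,
                             gap = 8)
  map <- simulate_noisy_map(truth, resolution = 25, noise_sd = 0,
                            voxel = 4, seed = seed)
  list(truth = truth, map = map)
}

# the standard end-to-end fixture (built once; used by several files)
std_fixture <- function() cached("std_fixture", function() {
  elongator_like_fixture(seed = 1)
})

# quaternion angle in degrees
quat_angle_deg <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d) * 180 / pi
}

# pose error of a fit-library row against a set of true poses
fit_errors <- function(lib_row, true_poses) {
  q <- as.numeric(lib_row[c("qw", "qx", "qy", "qz")])
  t <- as.numeric(lib_row[c("tx", "ty", "tz")])
  errs <- vapply(true_poses, function(tp)
    c(sqrt(sum((t - tp$t)^2)), quat_angle_deg(q, tp$q)), numeric(2))
  errs[, which.min(errs[1, ]), drop = TRUE]
}

# a strongly chiral body: Calpha trace of a right-handed solenoid
helix_model <- function(n = 80, radius = 14, pitch = 34) {
  t <- seq(0, 3.5 * 2 * pi, length.out = n)
  atomic_model(data.frame(
    chain = "A", resno = seq_len(n), resname = "ALA", elety = "CA",
    x = radius * cos(t), y = radius * sin(t), z = pitch * t / (2 * pi),
    stringsAsFactors = FALSE))
}

# random density map on a small grid
random_map <- function(n = 8, voxel = 2, seed = 1) {
  set.seed(seed)
  density_map(array(rnorm(n^3), c(n, n, n)), voxel = voxel)
}

# direct-summation DFT of a 3D array (independent of fft())
direct_dft3 <- function(x) {
  d <- dim(x)
  W <- function(n) {
    k <- 0:(n - 1)
    exp(-2i * pi * outer(k, k) / n)
  }
  w1 <- W(d[1]); w2 <- W(d[2]); w3 <- W(d[3])
  out <- array(0i, d)
  tmp <- array(0i, d)
  for (j in 1:d[2]) for (k in 1:d[3]) tmp[, j, k] <- w1 %*% x[, j, k]
  tmp2 <- array(0i, d)
  for (i in 1:d[1]) for (k in 1:d[3]) tmp2[i, , k] <- w2 %*% tmp[i, , k]
  for (i in 1:d[1]) for (j in 1:d[2]) out[i, j, ] <- w3 %*% tmp2[i, j, ]
  out
}

# brute-force FSC from a direct DFT, shell width one Fourier voxel
direct_fsc <- function(mapA, mapB) {
  FA <- direct_dft3(mapA$values)
  FB <- direct_dft3(mapB$values)
  d <- dim(mapA$values)
  fax <- function(n) c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
  f <- sqrt(outer(outer(fax(d[1])^2, fax(d[2])^2, "+"), fax(d[3])^2, "+"))
  n <- min(d)
  shell <- round(f * n)
  keep <- shell <= floor(n / 2)
  num <- tapply(Re(FA * Conj(FB))[keep], shell[keep], sum)
  pa <- tapply((Mod(FA)^2)[keep], shell[keep], sum)
  pb <- tapply((Mod(FB)^2)[keep], shell[keep], sum)
  as.numeric(num / sqrt(pa * pb))
}
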