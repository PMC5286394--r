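test_that("simulated density is localized, linear, and mass-conserving", {
  one <- atomic_model(data.frame(chain = "A", resno = 1L, resname = "ALA",
                                 elety = "CA", x = 0.4, y = -0.2, z = 0.1))
  m <- simulate_density(one, resolution = 10, voxel = 2, padding = 12)
  peak <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  peak_pos <- m$origin + (peak - 1) * m$voxel
  expect_lt(max(abs(peak_pos - c(0.4, -0.2, 0.1))), m$voxel)

  # doubling bead masses doubles the map exactly
  beads <- coarse_grain(line_model(20))
  m1 <- simulate_density(beads, resolution = 12, voxel = 2)
  beads2 <- beads; beads2$span <- beads2$span * 2
  m2 <- simulate_density(beads2, resolution = 12, voxel = 2)
  expect_equal(m2$values, 2 * m1$values)

  # quadrature: integral x voxel^3 equals the total weight within 1%
  body <- small_body_case()$body
  mm <- simulate_density(body, resolution = 20, voxel = 2, padding = 25)
  total <- sum(mm$values) * mm$voxel^3
  expect_lt(abs(total - nrow(body$atoms)) / nrow(body$atoms), 0.01)

  expect_error(simulate_density(one, resolution = 3, voxel = 2), "twice")
})

test_that("normalized cross-correlation behaves like Pearson r", {
  m <- simulate_density(small_body_case()$body, resolution = 20, voxel = 4)
  expect_equal(ncc(m, m), 1.0)

  # affine invariance for a > 0
  m2 <- m; m2$values <- 3.7 * m2$values + 0.5
  expect_equal(ncc(m, m2, mask = "all"), 1.0)

  # 2x2x2 hand-computed case: B is A reversed -> r = -1
  A <- density_map(array(0:7, c(2, 2, 2)), voxel = 1)
  B <- density_map(array(7:0, c(2, 2, 2)), voxel = 1)
  expect_equal(ncc(A, B, mask = "all"), -1.0)
  # matches the direct summation oracle
  expect_equal(ncc(A, B, mask = "all"),
               cor(as.numeric(A$values), as.numeric(B$values)))

  cst <- density_map(array(1, c(4, 4, 4)), voxel = 1)
  expect_error(ncc(cst, cst, mask = "all"), "constant")
  z <- density_map(array(0, c(4, 4, 4)), voxel = 1)
  expect_error(ncc(z, z, mask = "overlap"), "empty mask")
})

test_that("low-pass filtering preserves the mean and composes as Gaussians", {
  cst <- density_map(array(5, c(8, 8, 8)), voxel = 2)
  expect_equal(lowpass_filter(cst, 10)$values, cst$values, tolerance = 1e-12)

  m <- random_map(16, voxel = 2, seed = 4)
  f1 <- lowpass_filter(lowpass_filter(m, 10), 10)
  f2 <- lowpass_filter(m, 10 * sqrt(2))
  expect_equal(f1$values, f2$values, tolerance = 1e-10)
  expect_equal(mean(f1$values), mean(m$values), tolerance = 1e-12)
  expect_lt(var(as.numeric(lowpass_filter(m, 12)$values)),
            var(as.numeric(m$values)))
})

test_that("mirroring is an involution and detects chirality", {
  m <- random_map(10, voxel = 2, seed = 5)
  expect_identical(mirror_map(mirror_map(m))$values, m$values)

  # a chiral 4-point constellation correlates imperfectly with its mirror
  chiral <- atomic_model(data.frame(
    chain = "A", resno = 1:4, resname = "ALA", elety = "CA",
    x = c(0, 10, 0, 3), y = c(0, 0, 10, 4), z = c(0, 0, 0, 8)))
  cm <- simulate_density(chiral, resolution = 8, voxel = 2, padding = 10)
  expect_lt(ncc(cm, mirror_map(cm), mask = "all"), 1)
})

test_that("cyclic symmetrization averages over the group", {
  fx <- std_fixture()
  sym <- apply_symmetry(fx$map_scaffold, 2)
  # C2 on an (almost) C2 map changes little; C2 twice equals C2 once
  expect_gt(ncc(fx$map_scaffold, sym, mask = "all"), 0.99)
  expect_equal(apply_symmetry(sym, 2)$values, sym$values, tolerance = 1e-12)
  # exact index path preserves the mean exactly
  expect_identical(mean(sym$values), mean(fx$map_scaffold$values))
  # trilinear path for other orders preserves the mean approximately
  s3 <- apply_symmetry(fx$map_scaffold, 3)
  expect_equal(mean(s3$values), mean(fx$map_scaffold$values),
               tolerance = 0.05)
  expect_error(apply_symmetry(fx$map_scaffold, 1), "order")
})

test_that("difference maps localize added density", {
  m <- random_map(12, voxel = 3, seed = 6)
  d0 <- difference_map(m, m, common_resolution = 12)
  expect_equal(max(abs(d0$values)), 0, tolerance = 1e-12)

  # A = B + localized blob -> maximum inside the blob support
  blob <- atomic_model(data.frame(chain = "A", resno = 1:3, resname = "ALA",
                                  elety = "CA", x = c(20, 22, 24),
                                  y = 20, z = 20))
  base <- small_body_case()$body
  mb <- simulate_density(base, resolution = 14, voxel = 2, padding = 30)
  madd <- simulate_density(blob, resolution = 14, voxel = 2, grid = mb)
  ma <- mb; ma$values <- mb$values + madd$values
  dd <- difference_map(ma, mb, common_resolution = 14)
  peak <- which(dd$values == max(dd$values), arr.ind = TRUE)[1, ]
  peak_pos <- dd$origin + (peak - 1) * dd$voxel
  expect_lt(sqrt(sum((peak_pos - c(22, 20, 20))^2)), 10)

  # antisymmetry
  dr <- difference_map(mb, ma, common_resolution = 14)
  expect_equal(dr$values, -dd$values, tolerance = 1e-10)
})

test_that("FSC matches its definition and the direct-summation oracle", {
  m <- random_map(8, voxel = 2, seed = 7)
  self <- fsc(m, m)
  expect_true(all(abs(self$fsc - 1) < 1e-9))
  neg <- m; neg$values <- -neg$values
  expect_true(all(abs(fsc(m, neg)$fsc + 1) < 1e-9))

  m2 <- random_map(8, voxel = 2, seed = 8)
  expect_equal(fsc(m, m2)$fsc, direct_fsc(m, m2), tolerance = 1e-6)

  # independent white-noise maps: per-shell FSC consistent with zero
  a <- random_map(16, voxel = 2, seed = 9)
  b <- random_map(16, voxel = 2, seed = 10)
  fab <- fsc(a, b)
  ok <- fab$n_voxels > 8
  expect_true(all(abs(fab$fsc[ok]) < 3 / sqrt(fab$n_voxels[ok])))
})

test_that("resolution_at interpolates the first downward crossing", {
  curve <- data.frame(freq = c(0.01, 0.02, 0.03, 0.04),
                      fsc = c(1, 0.8, 0.2, 0.1),
                      n_voxels = 100L)
  class(curve) <- c("fsc_curve", "data.frame")
  # crossing of 0.5 between 0.02 and 0.03: f = 0.02 + 0.3/0.6 * 0.01
  expect_equal(as.numeric(resolution_at(curve, 0.5)), 1 / 0.025)
  expect_true(attr(resolution_at(curve, 0.5), "crossed"))
  # a never-crossing curve returns Nyquist with a flag
  flat <- curve; flat$fsc <- rep(0.9, 4)
  r <- resolution_at(flat, 0.5, voxel = 2)
  expect_equal(as.numeric(r), 4)
  expect_false(attr(r, "crossed"))
})

test_that("volume coverage reflects the modeled fraction of the map", {
  body <- small_body_case()$body
  m <- simulate_density(body, resolution = 18, voxel = 3)
  beads <- coarse_grain(body)
  expect_equal(volume_coverage(m, beads, radius_scale = 3), 1.0)
  expect_equal(volume_coverage(m, beads[0, ]), 0.0)

  # two-blob map with only one blob modeled -> about half covered
  far <- body
  far$atoms$x <- far$atoms$x + 90
  both <- rbind(body$atoms, transform(far$atoms, chain = "B"))
  two <- simulate_density(atomic_model(both), resolution = 18, voxel = 3)
  half <- volume_coverage(two, beads, radius_scale = 2)
  expect_gt(half, 0.45)
  expect_lt(half, 0.55)

  expect_error(volume_coverage(m, beads, contour = max(m$values) * 2),
               "contour")
})
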