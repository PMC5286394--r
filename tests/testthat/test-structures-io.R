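test_that("PDB read-back preserves atoms and author numbering", {
  path <- withr::local_tempfile(fileext = ".pdb")
  m <- atomic_model(data.frame(chain = "A", resno = 7L, resname = "ALA",
                               elety = "CA", x = 1, y = 2, z = 3))
  write_structure(m, path)
  m2 <- read_structure(path)
  expect_equal(nrow(m2$atoms), 1L)
  expect_equal(m2$atoms$resno, 7L)
  expect_equal(as.numeric(m2$atoms[1, c("x", "y", "z")]), c(1, 2, 3))

  # round-trip of a multi-chain model's CA coordinates
  set.seed(11)
  big <- generate_assembly(2, body_size = 40, seed = 2)$model
  write_structure(big, path)
  back <- read_structure(path)
  expect_equal(ca_xyz(calpha(back)), ca_xyz(calpha(big)),
               tolerance = 1e-3)  # PDB fixed-width precision
  expect_setequal(names(back$subunit_of_chain),
                  names(big$subunit_of_chain))
})

test_that("atomic_model enforces its invariants", {
  base <- data.frame(chain = "A", resno = c(1L, 1L), resname = "ALA",
                     elety = "CA", x = 0, y = 0, z = 0)
  expect_error(atomic_model(base), "duplicate residue")
  bad <- base; bad$resno <- 1:2; bad$x[1] <- NaN
  expect_error(atomic_model(bad), "non-finite")
  expect_error(atomic_model(base[0, ]), "empty")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("MRC maps round-trip losslessly and honor the origin", {
  path <- withr::local_tempfile(fileext = ".mrc")
  z <- density_map(array(0, c(8, 8, 8)), voxel = 3, origin = c(10, 10, 10))
  write_density(z, path)
  z2 <- read_density(path)
  expect_identical(z2$values, z$values)
  expect_equal(z2$voxel, 3)
  # physical coordinate of voxel (0,0,0) is the origin
  expect_equal(z2$origin, c(10, 10, 10))
  expect_equal(sapply(voxel_axes(z2), `[`, 1), z2$origin,
               ignore_attr = TRUE)

  # float32 is the container precision: a second generation is bit-exact
  m <- random_map(16, voxel = 2.5, seed = 2)
  write_density(m, path)
  g1 <- read_density(path)
  write_density(g1, path)
  g2 <- read_density(path)
  expect_identical(g1$values, g2$values)
  expect_lt(max(abs(g1$values - m$values)), 1e-6)
})

test_that("an independent MRC reader agrees with the writer", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  path <- withr::local_tempfile(fileext = ".mrc")
  m <- random_map(8, voxel = 2.5, seed = 3)
  m$origin <- c(4, 5, 6)
  write_density(m, path)
  out <- tryCatch(system2("python", c("-c", shQuote(paste0(
    "import gemmi,numpy;g=gemmi.read_ccp4_map('", path, "');",
    "a=numpy.array(g.grid,copy=False);",
    "print(g.grid.nu,g.grid.nv,g.grid.nw,round(g.grid.spacing[0],6),",
    "round(float(a[1,2,3]),6),g.header_float(50),g.header_float(51),",
    "g.header_float(52))"))), stdout = TRUE, stderr = TRUE),
    warning = function(w) NA)
  skip_if(length(out) != 1 || is.na(out), "python/gemmi unavailable")
  f <- as.numeric(strsplit(trimws(out), " ")[[1]])
  expect_equal(f[1:3], c(8, 8, 8))
  expect_equal(f[4], 2.5)
  expect_equal(f[5], round(m$values[2, 3, 4], 6))  # gemmi indexes [x,y,z]
  expect_equal(f[6:8], c(4, 5, 6))
})

test_that("crosslink tables filter inclusively and collapse duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(Protein1 = c("A", "A", "A", "B"),
                   AbsPos1 = c(10L, 20L, 30L, 12L),
                   Protein2 = c("B", "B", "B", "A"),
                   AbsPos2 = c(5L, 6L, 7L, 401L),
                   linker = "DSS",
                   `ld-score` = c(25, 30, 41, 35), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  xl <- read_crosslink_table(path)
  expect_equal(nrow(xl), 3L)                 # 25 dropped, threshold inclusive
  expect_true(all(xl$ld_score >= 30))

  # unordered duplicate collapses keeping the max score
  df2 <- data.frame(Protein1 = c("A", "B"), AbsPos1 = c(401L, 12L),
                    Protein2 = c("B", "A"), AbsPos2 = c(12L, 401L),
                    linker = "DSS", `ld-score` = c(33, 39),
                    check.names = FALSE)
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  xl2 <- read_crosslink_table(path)
  expect_equal(nrow(xl2), 1L)
  expect_equal(xl2$ld_score, 39)

  # filtering is idempotent
  expect_identical(crosslink_table(xl2, min_ld = 30), xl2)

  # missing column -> schema error naming it
  write.table(df[, -2], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_crosslink_table(path), "residue1")
})

test_that("a network-shaped table reports its inter/intra split", {
  # a synthetic identification table shaped like a six-subunit complex:
  # 116 unique links, 41 inter-subunit and 75 intra-subunit
  set.seed(42)
  prots <- paste0("P", 1:6)
  inter <- t(combn(prots, 2))
  inter <- inter[sample(nrow(inter), 41, replace = TRUE), , drop = FALSE]
  rows_inter <- data.frame(protein1 = inter[, 1],
                           residue1 = sample(500, 41),
                           protein2 = inter[, 2],
                           residue2 = sample(500, 41))
  p_intra <- sample(prots, 75, replace = TRUE)
  r1 <- sample(500, 75, replace = TRUE)
  rows_intra <- data.frame(protein1 = p_intra, residue1 = r1,
                           protein2 = p_intra, residue2 = r1 + sample(5:100, 75, replace = TRUE))
  df <- rbind(rows_inter, rows_intra)
  df$linker <- "DSS"
  df$ld_score <- runif(nrow(df), 30, 60)
  xl <- crosslink_table(df, min_ld = 30)
  expect_equal(nrow(xl), 116L)
  net <- crosslink_network_summary(xl)
  expect_equal(net$n_inter, 41L)
  expect_equal(net$n_intra, 75L)
  expect_equal(net$n_inter + net$n_intra, nrow(xl))
})

test_that("rigid-body segmentation derives linker counts from gaps", {
  m <- line_model(100)
  b <- segment_rigid_bodies(m, data.frame(
    body = c("n", "c"), chain = "A", start = c(1, 51), end = c(50, 100)))
  expect_equal(b$n$linker_neighbors$n_linker, 0L)

  b2 <- segment_rigid_bodies(m, data.frame(
    body = c("n", "c"), chain = "A", start = c(1, 61), end = c(40, 100)))
  expect_equal(b2$n$linker_neighbors$n_linker, 20L)

  # a 1349-residue chain split around a 945-960 hinge leaves a
  # 16-residue flexible linker between the two arms
  long <- line_model(1349)
  b3 <- segment_rigid_bodies(long, data.frame(
    body = c("arm1", "arm2"), chain = "A",
    start = c(1, 961), end = c(944, 1349)))
  expect_equal(b3$arm1$linker_neighbors$n_linker, 16L)

  expect_error(segment_rigid_bodies(m, data.frame(
    body = c("x", "y"), chain = "A", start = c(1, 40), end = c(50, 90))),
    "overlap")
})

test_that("coarse-graining conserves residues and centroids", {
  m <- line_model(10)
  b <- coarse_grain(m)
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$x, b$y, b$z), colMeans(ca_xyz(calpha(m))),
               ignore_attr = TRUE)

  b25 <- coarse_grain(line_model(25))
  expect_equal(b25$span, c(10L, 10L, 5L))

  # bead centroid equals the brute-force mean of its member residues,
  # and spans always partition the structured residues
  set.seed(9)
  truth <- generate_assembly(2, body_size = c(37, 61), seed = 7)
  beads <- coarse_grain(truth$model)
  ca <- calpha(truth$model)
  expect_equal(sum(beads$span), nrow(ca))
  for (i in sample(nrow(beads), 5)) {
    sel <- ca$chain == beads$chain[i] & ca$resno >= beads$res_start[i] &
      ca$resno <= beads$res_end[i]
    expect_equal(as.numeric(beads[i, c("x", "y", "z")]),
                 colMeans(ca_xyz(ca[sel, ])), ignore_attr = TRUE)
  }
  expect_error(coarse_grain(line_model(10)$atoms[0, ]), "no CA")
})
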