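# helper: a two-copy model with controllable positions
two_copy_model <- function(offset2 = c(0, 0, 40)) {
  at <- rbind(
    data.frame(chain = "A", resno = 1:3, resname = "ALA", elety = "CA",
               x = c(0, 3.8, 7.6), y = 0, z = 0),
    data.frame(chain = "B", resno = 1:3, resname = "ALA", elety = "CA",
               x = c(0, 3.8, 7.6) + offset2[1], y = offset2[2],
               z = offset2[3]))
  atomic_model(at, subunits = c(A = "P", B = "P"),
               copies = c(A = 1L, B = 2L))
}

test_that("crosslink distances resolve copy ambiguity by the minimum", {
  m <- atomic_model(rbind(
    data.frame(chain = "A", resno = 1L, resname = "ALA", elety = "CA",
               x = 0, y = 0, z = 0),
    data.frame(chain = "B", resno = 1L, resname = "ALA", elety = "CA",
               x = 0, y = 0, z = 21)))
  xl <- crosslink_table(data.frame(protein1 = "A", residue1 = 1L,
                                   protein2 = "B", residue2 = 1L,
                                   linker = "DSS", ld_score = 35))
  d <- crosslink_distances(m, xl)
  expect_equal(d$distance, 21.0)

  # two copies at 40 and 25 A -> 25 reported
  mc <- two_copy_model(offset2 = c(0, 0, 40))
  other <- atomic_model(data.frame(chain = "C", resno = 1L,
                                   resname = "ALA", elety = "CA",
                                   x = 0, y = 25, z = 40),
                        subunits = c(C = "Q"))
  both <- atomic_model(rbind(mc$atoms, other$atoms),
                       subunits = c(A = "P", B = "P", C = "Q"),
                       copies = c(A = 1L, B = 2L, C = 1L))
  xl2 <- crosslink_table(data.frame(protein1 = "P", residue1 = 1L,
                                    protein2 = "Q", residue2 = 1L,
                                    linker = "DSS", ld_score = 35))
  # copy A at dist sqrt(25^2+40^2) ~ 47.2; copy B at 25
  expect_equal(crosslink_distances(both, xl2)$distance, 25.0)
})

test_that("dimeric links must cross copies", {
  dimeric <- crosslink_table(data.frame(protein1 = "P", residue1 = 2L,
                                        protein2 = "P", residue2 = 2L,
                                        linker = "DSS", ld_score = 40))
  expect_true(dimeric$is_dimeric)
  one_copy <- atomic_model(
    data.frame(chain = "A", resno = 1:3, resname = "ALA", elety = "CA",
               x = c(0, 3.8, 7.6), y = 0, z = 0),
    subunits = c(A = "P"))
  d1 <- crosslink_distances(one_copy, dimeric)
  expect_false(d1$mappable)           # unmappable, counted not dropped

  m2 <- two_copy_model(offset2 = c(0, 0, 18))
  d2 <- crosslink_distances(m2, dimeric)
  expect_true(d2$mappable)
  expect_equal(d2$distance, 18.0)
  expect_false(d2$chain1 == d2$chain2)
})

test_that("the crosslink penalty is soft, capped, and monotone", {
  expect_equal(crosslink_restraint(c(10, 29.9, 30)), 0)
  expect_equal(crosslink_restraint(33, threshold = 30, sigma = 3), 1)
  expect_equal(crosslink_restraint(200, cap = 9), 9)
  # monotone non-decreasing in every distance
  ds <- seq(5, 80, by = 2.5)
  pens <- vapply(ds, crosslink_restraint, 0)
  expect_true(all(diff(pens) >= 0))
  expect_error(crosslink_restraint(10, threshold = 0), "threshold")
})

test_that("connectivity allows full linker extension plus slack", {
  m <- line_model(100)
  bodies <- segment_rigid_bodies(m, data.frame(
    body = c("n", "c"), chain = "A", start = c(1, 51), end = c(50, 100)))
  # adjacent domains with touching termini
  expect_equal(connectivity_restraint(m, bodies), 0)

  # a 10-residue linker spanning exactly 38 A (10 x 3.8) costs nothing
  mk_gap <- function(gap_A) {
    at <- line_model(40)$atoms
    at$resno[21:40] <- 31:50                 # 10-residue sequence gap
    at$x[21:40] <- at$x[20] + gap_A + (0:19) * 3.8
    atomic_model(at)
  }
  b2 <- function(m) segment_rigid_bodies(m, data.frame(
    body = c("n", "c"), chain = "A", start = c(1, 31), end = c(20, 50)))
  m38 <- mk_gap(38)
  expect_equal(connectivity_restraint(m38, b2(m38)), 0)
  m60 <- mk_gap(60)
  pen <- connectivity_restraint(m60, b2(m60))
  expect_gt(pen, 0)
  expect_equal(pen, ((60 - (10 * 3.8 + 5)) / 3)^2)
})

test_that("clash score matches the all-pairs oracle exactly", {
  set.seed(17)
  n <- 50
  beads <- data.frame(x = runif(n, 0, 40), y = runif(n, 0, 40),
                      z = runif(n, 0, 40), radius = runif(n, 3, 8),
                      span = 10L, body = sample(c("a", "b", "c"), n, TRUE))
  class(beads) <- c("bead_model", "data.frame")
  oracle <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (beads$body[i] == beads$body[j]) next
    d <- sqrt(sum((as.numeric(beads[i, 1:3]) - as.numeric(beads[j, 1:3]))^2))
    oracle <- oracle + max(0, beads$radius[i] + beads$radius[j] - d)^2
  }
  expect_equal(clash_score(beads), oracle)

  apart <- beads; apart$x <- apart$x + 200 * as.integer(factor(apart$body))
  expect_equal(clash_score(apart), 0)

  # superposing two identical bodies maximizes the overlap penalty
  a <- beads[beads$body == "a", ]
  b2 <- a; b2$body <- "b"
  sup <- rbind(a, b2)
  class(sup) <- c("bead_model", "data.frame")
  apart2 <- sup; apart2$x[sup$body == "b"] <- apart2$x[sup$body == "b"] + 15
  expect_gt(clash_score(sup), clash_score(apart2))
})

test_that("the composite score is an exact weighted sum and linear", {
  case <- two_body_case(seed = 31)
  truth <- case$truth
  xl <- simulate_crosslinks(truth, 12, decoy_fraction = 0, seed = 2)
  sc <- composite_score(truth$model, truth$bodies, xl,
                        em_ncc = c(0.9, 0.8))
  expect_equal(sc$total,
               sc$weights[1] * sc$em + sc$weights[2] * sc$xl +
                 sc$weights[3] * sc$conn + sc$weights[4] * sc$clash)
  expect_equal(sc$em, -(0.9 + 0.8))

  z <- composite_score(truth$model, truth$bodies, xl,
                       em_ncc = c(0.9, 0.8), weights = rep(0, 4))
  expect_equal(z$total, 0)

  # doubling w_xl doubles the xl contribution exactly
  w1 <- composite_score(truth$model, truth$bodies, xl,
                        em_ncc = c(0.9, 0.8),
                        weights = c(1, 1, 1, 0.1))
  w2 <- composite_score(truth$model, truth$bodies, xl,
                        em_ncc = c(0.9, 0.8),
                        weights = c(1, 2, 1, 0.1))
  expect_equal(w2$total - w1$total, w1$xl)
  expect_error(composite_score(truth$model, truth$bodies, xl,
                               weights = c(-1, 1, 1, 1)), "weights")
})

test_that("restraint terms are invariant under a global rigid motion", {
  case <- two_body_case(seed = 33)
  truth <- case$truth
  xl <- simulate_crosslinks(truth, 15, decoy_fraction = 0.1, seed = 3)
  sc0 <- composite_score(truth$model, truth$bodies, xl, em_ncc = c(0, 0))
  R <- axis_angle_matrix(c(1, 2, 0.5), 0.9)
  moved <- truth$model
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")]) %*% t(R)
  moved$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(12, -7, 30), "+")
  sc1 <- composite_score(moved, truth$bodies, xl, em_ncc = c(0, 0))
  expect_equal(sc1$xl, sc0$xl, tolerance = 1e-9)
  expect_equal(sc1$conn, sc0$conn, tolerance = 1e-9)
  expect_equal(sc1$clash, sc0$clash, tolerance = 1e-9)
})

test_that("ambiguity resolution never lowers the satisfaction fraction", {
  fx <- std_fixture()
  rep_amb <- satisfaction_report(fx$truth$model, fx$crosslinks)
  # force a fixed arbitrary copy choice by dropping copy-2 chains
  keep <- names(fx$truth$model$copy_of_chain)[
    fx$truth$model$copy_of_chain == 1L]
  m1 <- fx$truth$model
  m1$atoms <- m1$atoms[m1$atoms$chain %in% keep, ]
  m1 <- atomic_model(m1$atoms, m1$subunit_of_chain[keep],
                     m1$copy_of_chain[keep])
  rep_fixed <- satisfaction_report(m1, fx$crosslinks)
  expect_gte(rep_amb$fraction, rep_fixed$fraction)
})

test_that("satisfaction reports use the conventional wording", {
  # 30 link targets on a line: 28 close, 2 far
  mk <- function(n_close, n_far, far_d = 60) {
    n <- n_close + n_far
    at <- rbind(
      data.frame(chain = "A", resno = 1:n, resname = "ALA", elety = "CA",
                 x = (1:n) * 50, y = 0, z = 0),
      data.frame(chain = "B", resno = 1:n, resname = "ALA", elety = "CA",
                 x = (1:n) * 50, y = c(rep(10, n_close), rep(far_d, n_far)),
                 z = 0))
    m <- atomic_model(at, subunits = c(A = "PA", B = "PB"))
    xl <- crosslink_table(data.frame(
      protein1 = "PA", residue1 = 1:n, protein2 = "PB", residue2 = 1:n,
      linker = "DSS", ld_score = 40))
    satisfaction_report(m, xl)
  }
  expect_equal(mk(28, 2)$text, "28 out of 30 (93%)")
  expect_equal(mk(37, 2)$text, "37 out of 39 (95%)")
  r <- mk(5, 0)
  expect_equal(r$fraction, 1)

  empty <- satisfaction_report(line_model(5), crosslink_table(
    data.frame(protein1 = "Z", residue1 = 1L, protein2 = "Z",
               residue2 = 9L, linker = "DSS", ld_score = 40)))
  expect_true(empty$empty)
  expect_true(is.na(empty$fraction))
  expect_equal(empty$n_unmappable, 1L)
})
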